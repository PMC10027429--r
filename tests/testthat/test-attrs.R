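test_that("attribute tokens parse, case-fold and round-trip", {
  a <- parse_attr_fields(c("fill=green"))
  expect_s3_class(a, "attr_map")
  expect_equal(attrs_to_tokens(a), "fill=green")

  expect_length(parse_attr_fields(character(0)), 0L)

  # case-insensitive keys, last wins, order of first occurrence preserved
  expect_warning(a2 <- parse_attr_fields(c("fill=red", "stroke=black", "FILL=blue")),
                 "duplicate attribute key")
  expect_equal(attrs_to_tokens(a2), c("fill=blue", "stroke=black"))

  # values kept verbatim (including '=' inside the value)
  a3 <- parse_attr_fields("label=x=y")
  expect_equal(unname(unclass(a3)[["label"]]), "x=y")
})

test_that("malformed attribute tokens name file, line and token", {
  expect_error(parse_attr_fields("green", file = "f.txt", lineno = 7),
               "f.txt, line 7.*'green'")
  expect_error(parse_attr_fields("=green"), "empty key or value")
  expect_error(parse_attr_fields("fill="), "empty key or value")
})

test_that("serialization round-trips losslessly for random attr maps", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(0:6, 1)
    keys <- if (n > 0) paste0("k", sample(100, n)) else character(0)
    vals <- if (n > 0) paste0("v", sample(100, n)) else character(0)
    a <- attr_map(keys, vals)
    expect_equal(parse_attr_fields(attrs_to_tokens(a)), a)
  }
})
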