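test_that("unimodal sequences round-trip between items, codes and strings", {
  s <- unimodal_sequence("-H-V-V-V-V")
  expect_equal(s$items, c("H", "V", "V", "V", "V"))
  expect_equal(s$code, 15L)
  expect_equal(format(unimodal_sequence(15)), "-H-V-V-V-V")
  expect_equal(unimodal_sequence(0)$items, rep("H", 5))
  expect_equal(unimodal_sequence(31)$items, rep("V", 5))
  expect_error(unimodal_sequence("HHV"), "exactly 5")
  seqs <- enumerate_unimodal()
  expect_length(seqs, 32)
  expect_equal(vapply(seqs, function(x) x$code, integer(1)), 0:31)
})

test_that("crossmodal enumeration excludes the 32 strictly unimodal lists", {
  seqs <- enumerate_crossmodal()
  expect_length(seqs, 224)
  mods <- vapply(seqs, function(s) paste(substr(s$items, 1, 1), collapse = ""),
                 character(1))
  expect_false(any(mods %in% c("VVVV", "AAAA")))
  expect_error(crossmodal_sequence("VL-VH-VL-VH"), "unimodal")
  expect_s3_class(crossmodal_sequence("VL-VH-VL-VH", allow_unimodal = TRUE),
                  "crossmodal_sequence")
  expect_s3_class(crossmodal_sequence("AH-VL-VH-VH"), "crossmodal_sequence")
  strs <- vapply(seqs, format, character(1))
  expect_true("AH-VL-VH-VH" %in% strs)
})

test_that("Gabor frames are transposed orientations with five pixel classes", {
  for (res in c(20, 10)) {
    H <- render_gabor("H", res)
    V <- render_gabor("V", res)
    expect_identical(unclass(H), t(unclass(V)))
    expect_equal(H[1, 1], "0")                      # corner outside aperture
    expect_equal(H[1, res], "0")
    cls <- unique(paste(as.vector(H), as.vector(V)))
    expect_length(cls, 5)                           # 00, BB, WW, BW, WB
    expect_setequal(cls, c("0 0", "B B", "W W", "B W", "W B"))
  }
})

test_that("disc frames respect the midline and the chosen geometry", {
  res <- 20
  H <- render_disc("H", res)
  L <- render_disc("L", res)
  top_half <- seq_len(res / 2)      # rows 1..10 are above the midline
  expect_true(all(H[-top_half, ] == "0"))   # upper disc: nothing below
  expect_true(all(L[top_half, ] == "0"))    # lower disc: nothing above
  expect_true(any(H == "bright") && any(L == "bright"))
  expect_false(any(H == "bright" & L == "bright"))  # disjoint by default
  Ho <- render_disc("H", res, geometry = "overlap")
  Lo <- render_disc("L", res, geometry = "overlap")
  expect_true(any(Ho == "bright" & Lo == "bright"))  # shared central band
})

test_that("stream building reproduces the canonical per-pixel patterns", {
  s <- unimodal_sequence("-H-V-V-V-V")
  b <- build_streams(s, repetitions = 2, resolution = 10)
  expect_equal(dim(b$streams), c(100, 20))
  H <- render_gabor("H", 10); V <- render_gabor("V", 10)
  bw <- which(H == "B" & V == "W")[1]   # location 1: differs between items
  ww <- which(H == "W" & V == "W")[1]   # location 2: same in all items
  bg <- which(H == "0")[1]
  expect_equal(paste(b$streams[bw, 1:10], collapse = ""), "0B0W0W0W0W")
  expect_equal(paste(b$streams[ww, 1:10], collapse = ""), "0W0W0W0W0W")
  expect_true(all(b$streams[bg, ] == "0"))
  bt <- build_streams(s, repetitions = 2, test_item = "V", resolution = 10)
  expect_equal(ncol(bt$streams), 22)    # +2 steps for the test item
  expect_equal(bt$test_step, 22)
})

test_that("crossmodal streams route modalities to their channels", {
  s <- crossmodal_sequence("AH-VL-VH-VH")
  b <- build_streams(s, repetitions = 1, resolution = 10)
  expect_equal(nrow(b$streams), 101)    # 100 pixels + 1 auditory channel
  aud <- b$streams[101, ]
  expect_equal(aud[2], "high")          # the auditory item
  expect_true(all(aud[-2] == "0"))      # silent elsewhere
  expect_true(all(b$streams[1:100, 2] == "0"))  # no visual input on A items
  expect_true(any(b$streams[1:100, 4] == "bright"))  # VL frame present
})

test_that("test items continue or violate the cyclic sequence", {
  s <- unimodal_sequence("-V-H-V-V-V")
  expect_equal(make_test_item(s, 6, congruent = TRUE), "V")
  expect_equal(make_test_item(s, 6, congruent = FALSE), "H")
  expect_equal(make_test_item(s, 7, congruent = TRUE), "H")
  # 20 repetitions of -H-V-V-V-V: the due item at position 101 is H, flip -> V
  s2 <- unimodal_sequence("-H-V-V-V-V")
  expect_equal(make_test_item(s2, 101, congruent = TRUE), "H")
  expect_equal(make_test_item(s2, 101, congruent = FALSE), "V")
  cs <- crossmodal_sequence("AH-VL-VH-VH")
  expect_equal(make_test_item(cs, 5, congruent = TRUE), "AH")
  expect_equal(make_test_item(cs, 5, congruent = FALSE), "AL")  # level flips
})

test_that("sequence entropy takes the three closed-form values", {
  expect_equal(sequence_entropy(unimodal_sequence("HHHHH")), 0)
  expect_equal(sequence_entropy(unimodal_sequence("HVVVV")),
               -(0.2 * log2(0.2) + 0.8 * log2(0.8)), tolerance = 1e-12)
  expect_equal(sequence_entropy(unimodal_sequence("HHVVV")),
               -(0.4 * log2(0.4) + 0.6 * log2(0.6)), tolerance = 1e-12)
  ents <- vapply(enumerate_unimodal(), sequence_entropy, numeric(1))
  expect_length(unique(round(ents, 9)), 3)
  # crossmodal entropy is over feature levels, not modalities
  expect_equal(sequence_entropy(crossmodal_sequence("AL-VH-VH-VH")),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-12)
})

test_that("raw input streams parse, validate and round-trip through text", {
  b <- input_streams("0W0W0W0W0W", repetitions = 3)
  expect_equal(dim(b$streams), c(1, 30))
  b2 <- input_streams(c("0 W 0 B", "0 0 0 W"))
  expect_equal(dim(b2$streams), c(2, 4))
  expect_error(input_streams("0X0W"), "not in target map")
  expect_error(input_streams(c("0W", "0WW")), "equal length")
  path <- withr::local_tempfile(fileext = ".txt")
  write_streams(b2, path)
  b3 <- read_streams(path)
  expect_identical(unname(b3$streams), unname(b2$streams))
})
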