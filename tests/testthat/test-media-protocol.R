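test_that("default protocol reproduces the published media gradient", {
  p <- build_default_protocol()
  s <- p$segments
  expect_equal(s$medium, c("FaSSGF", "FaSSIF-V2", "FaSSIF-V2 midgut",
                           "SIF Ileum-V2", "FaSSCoF"))
  expect_equal(s$start, c(0, 30, 70, 150, 210))
  expect_equal(s$duration, c(30, 40, 80, 60, 150))
  expect_equal(s$flow_rate, c(8, 4, 4, 4, 4))
  expect_equal(protocol_end(p), 360)   # 6 h experiment

  # lower-intestinal maleate media carry the printed compositions
  expect_equal(p$media[["FaSSIF-V2 midgut"]]$pH, 6.8)
  expect_equal(p$media[["SIF Ileum-V2"]]$pH, 7.5)
  expect_equal(p$media[["FaSSCoF"]]$pH, 7.8)
  expect_equal(p$media[["FaSSIF-V2 midgut"]]$buffer_total, 19.3)
  expect_equal(p$media[["SIF Ileum-V2"]]$buffer_total, 52.8)
  expect_equal(p$media[["FaSSCoF"]]$buffer_total, 75.8)
  expect_equal(p$media[["FaSSIF-V2 midgut"]]$bile_salt, 1.5)
  expect_equal(p$media[["SIF Ileum-V2"]]$bile_salt, 0.8)
  expect_equal(p$media[["FaSSCoF"]]$bile_salt, 0)
  for (m in c("FaSSIF-V2 midgut", "SIF Ileum-V2", "FaSSCoF")) {
    expect_equal(p$media[[m]]$buffer_pka1, 1.83)
    expect_equal(p$media[[m]]$buffer_pka2, 5.99)
  }
})

test_that("segment intervals partition the protocol span exactly", {
  p <- build_default_protocol()
  s <- p$segments
  expect_equal(s$start[1], 0)
  expect_equal(s$start[-1], (s$start + s$duration)[-nrow(s)])
  expect_equal(sum(s$duration), protocol_end(p))
})

test_that("medium_at uses half-open intervals, right-continuous at switches", {
  p <- build_default_protocol()
  expect_equal(medium_at(p, 0)$name, "FaSSGF")
  # boundary belongs to the incoming medium
  expect_equal(medium_at(p, 150)$name, "SIF Ileum-V2")
  expect_equal(medium_at(p, 30)$name, "FaSSIF-V2")
  expect_equal(medium_at(p, 359)$name, "FaSSCoF")
  expect_equal(medium_at(p, 360)$name, "FaSSCoF")  # end maps to last medium
  # piecewise constant within each segment
  for (i in seq_len(nrow(p$segments))) {
    a <- p$segments$start[i]
    expect_equal(medium_at(p, a + 1e-9)$name, p$segments$medium[i])
    expect_equal(medium_at(p, a + p$segments$duration[i] / 2)$name,
                 p$segments$medium[i])
  }
  expect_error(medium_at(p, -1), "outside")
  expect_error(medium_at(p, 361), "outside")
})

test_that("validate_protocol reports violations as data", {
  p <- build_default_protocol()
  expect_identical(validate_protocol(p), character(0))

  bad <- p
  bad$segments$start[3] <- 60   # overlaps segment 2
  expect_match(paste(validate_protocol(bad), collapse = "; "), "overlap")

  bad <- p
  bad$segments$flow_rate[2] <- -4
  expect_match(paste(validate_protocol(bad), collapse = "; "), "flow_rate")

  bad <- p
  bad$segments$start[2] <- 35   # leaves a gap
  expect_match(paste(validate_protocol(bad), collapse = "; "), "gap")

  bad <- p
  bad$region_map[["FaSSCoF"]] <- NULL
  expect_match(paste(validate_protocol(bad), collapse = "; "), "Colon")
})

test_that("medium invariants are enforced", {
  expect_error(medium("x", pH = 0.5, solubility = 1), "pH")
  expect_error(medium("x", pH = 7, solubility = 0), "solubility")
  expect_error(medium("x", pH = 7, bile_salt = -1, solubility = 1), "bile")
})

test_that("protocol and media round-trip through the YAML config", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  p1 <- config_protocol(cfg)
  p2 <- config_protocol(cfg2)
  expect_equal(p1$segments, p2$segments)
  expect_equal(p1$media, p2$media)
  expect_equal(p1$cell_volume, p2$cell_volume)
})
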