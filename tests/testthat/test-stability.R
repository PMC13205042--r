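test_that("canonical component windows match the analysis protocol", {
  w <- componentWindows()
  expect_identical(w$name, c("click", "full_sabr", "onset", "ffr", "offset"))
  expect_equal(w$start_ms, c(1, 0, 5, 22, 45))
  expect_equal(w$end_ms, c(8, 55, 10, 40, 50))
  expect_error(componentWindows("sustained"), "unknown")
})

test_that("window slicing is half-open with floor indexing", {
  avg <- mkAvg(seq_len(1200))
  expect_length(windowSlice(avg, componentWindows("full_sabr")), 1100L)
  expect_length(windowSlice(avg, componentWindows("onset")), 100L)
  ## onset [5,10) and ffr [22,40) never share samples with neighbours
  on <- windowSlice(avg, componentWindows("onset"))
  ffr <- windowSlice(avg, componentWindows("ffr"))
  expect_length(intersect(on, ffr), 0L)
  ## whole epoch is the identity slice
  expect_identical(windowSlice(avg, list(start_ms = -5, end_ms = 55)),
                   avg@amplitude)
  expect_error(windowSlice(avg, list(start_ms = -10, end_ms = 5)), "epoch")
  expect_error(windowSlice(avg, list(start_ms = 10, end_ms = 5)), "precede")
})

test_that("subaverages balance polarity, channel and sweep counts exactly", {
  n <- 12
  mk <- function(v, ch, pol) mkBuf(matrix(v, n, 500), ch, pol)
  sub <- buildSubaverages(mk(1, "A", "condensation"),
                          mk(3, "A", "rarefaction"),
                          mk(2, "B", "condensation"),
                          mk(4, "B", "rarefaction"))
  ## constant-buffer oracle: (1 + 4)/2 and (2 + 3)/2
  expect_equal(unique(amplitude(sub$sub1)), 2.5)
  expect_equal(unique(amplitude(sub$sub2)), 2.5)
  for (s in sub) {
    comp <- composition(s)
    expect_equal(sum(comp$n), 2L * n)
    expect_equal(sum(comp$n[comp$polarity == "condensation"]), n)
    expect_equal(sum(comp$n[comp$channel == "A"]), n)
  }
  ## disjointness: sub1 draws on A-cond/B-rare, sub2 on B-cond/A-rare
  expect_length(intersect(sub$sub1@provenance, sub$sub2@provenance), 0L)

  zero <- buildSubaverages(mk(0, "A", "condensation"),
                           mk(0, "A", "rarefaction"),
                           mk(0, "B", "condensation"),
                           mk(0, "B", "rarefaction"))
  expect_true(all(amplitude(zero$sub1) == 0))
  expect_true(all(amplitude(zero$sub2) == 0))
})

test_that("mismatched buffer sets are rejected or truncated as configured", {
  mk <- function(n, ch, pol, t0 = -5) mkBuf(matrix(0, n, 500), ch, pol,
                                            t0 = t0)
  expect_error(buildSubaverages(mk(10, "A", "condensation"),
                                mk(10, "A", "rarefaction"),
                                mk(10, "B", "condensation"),
                                mk(8, "B", "rarefaction")), "unequal")
  tr <- buildSubaverages(mk(10, "A", "condensation"),
                         mk(10, "A", "rarefaction"),
                         mk(10, "B", "condensation"),
                         mk(8, "B", "rarefaction"), onUnequal = "truncate")
  expect_equal(sum(composition(tr$sub1)$n), 16L)
  expect_error(buildSubaverages(mk(10, "A", "condensation"),
                                mk(10, "A", "rarefaction"),
                                mk(10, "B", "condensation"),
                                mk(10, "B", "rarefaction", t0 = -4)),
               "timebase")
})

test_that("stability r behaves as a Pearson correlation must", {
  tt <- -5 + (0:1199) / 20
  s <- ifelse(tt >= 0, sin(2 * pi * 100 * tt / 1000), 0)
  a1 <- mkAvg(s)
  w <- list(start_ms = 0, end_ms = 50)
  expect_equal(stabilityR(a1, a1, w), 1)
  neg <- mkAvg(-s)
  expect_equal(stabilityR(a1, neg, w), -1)
  ## orthogonality over integer periods
  a2 <- mkAvg(ifelse(tt >= 0, cos(2 * pi * 100 * tt / 1000), 0))
  expect_lt(abs(stabilityR(a1, a2, w)), 1e-6)
  ## affine invariance in either argument
  aff <- mkAvg(3.7 * s + 2.2)
  expect_equal(stabilityR(a1, aff, w), 1, tolerance = 1e-12)
  expect_error(stabilityR(a1, mkAvg(rep(1, 1200)), w), "constant")
  short <- mkAvg(s[1:600], rate = 10000)
  expect_error(stabilityR(a1, short, w), "timebase")
})

test_that("Fisher transform is the clamped atanh", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.85), 1.25615, tolerance = 1e-5)
  expect_equal(fisherZ(1), atanh(1 - 1e-7))
  expect_error(fisherZ(1.01), "correlation")
  rs <- seq(-0.99, 0.99, length.out = 50)
  expect_true(all(diff(fisherZ(rs)) > 0))
})

test_that("a noiseless participant is perfectly stable on all five components", {
  da <- simDaBuffers(noiseModel(), 10, 100)
  clicks <- list(A = simulateSweeps(clickTpl, nSweeps = 10, channel = "A",
                                    seed = 1),
                 B = simulateSweeps(clickTpl, nSweeps = 10, channel = "B",
                                    seed = 2))
  tab <- stabilityTable(daBuffers = da, clickBuffers = clicks)
  expect_setequal(tab$component,
                  c("click", "full_sabr", "onset", "ffr", "offset"))
  expect_equal(tab$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(tab$z, rep(atanh(1 - 1e-7), 5), tolerance = 1e-6)
  ## click-only participants still yield a click record
  clickOnly <- stabilityTable(clickBuffers = clicks)
  expect_identical(clickOnly$component, "click")
})

test_that("noise-only stability is centred on zero", {
  nm <- noiseModel(noiseSd = 1)
  zeroTpl <- daTpl
  zeroTpl@amplitude <- numeric(length(daTpl@amplitude))
  rs <- vapply(1:50, function(s) {
    da <- simDaBuffers(nm, 40, s * 11, tpl = zeroTpl)
    tab <- stabilityTable(daBuffers = da)
    tab$r
  }, numeric(4))
  perComp <- rowMeans(rs)
  expect_true(all(abs(perComp) < 0.1))
})

test_that("balanced subaveraging cancels a polarity-flipping component", {
  nmP <- noiseModel(polarityComponentAmp = 0.5)
  da <- simDaBuffers(nmP, 40, 200)
  sub <- buildSubaverages(da$Acond, da$Arare, da$Bcond, da$Brare)
  ## the polarity component cancels exactly, so both subaverages equal the
  ## template and r = 1
  expect_lt(max(abs(amplitude(sub$sub1) - amplitude(daTpl))), 1e-12)
  expect_equal(stabilityR(sub$sub1, sub$sub2,
                          componentWindows("full_sabr")), 1)
  ## whereas a single-polarity average retains it
  singlePol <- colMeans(rbind(sweepData(da$Acond), sweepData(da$Bcond)))
  resid <- singlePol - amplitude(daTpl)
  expect_gt(sqrt(mean(resid^2)), 0.2)
})

test_that("collection-order split is disjoint and exhaustive", {
  buf <- simulateSweeps(clickTpl, noiseModel(noiseSd = 1), 11, seed = 5)
  h <- splitByCollection(buf)
  expect_equal(nSweeps(h$first), 6L)
  expect_equal(nSweeps(h$second), 5L)
  expect_identical(rbind(sweepData(h$first), sweepData(h$second)),
                   sweepData(buf))
  expect_identical(h$first@collectionIndex, 1L)
  expect_identical(h$second@collectionIndex, 2L)
  expect_error(splitByCollection(mkBuf(matrix(0, 1, 10))), "at least 2")
})
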