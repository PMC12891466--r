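test_that("layout templates expose the expected marker geometry", {
  lay <- load_layouts()
  expect_setequal(names(lay), c("3x4+II", "3x4", "6x2", "12x1"))

  g12 <- generate_layout(lay[["12x1"]])
  expect_equal(nrow(g12), 12)
  expect_equal(length(unique(g12$x)), 1) # one column
  expect_equal(diff(sort(g12$y)), rep(1 / 12, 11), tolerance = 1e-12)

  g34 <- generate_layout(lay[["3x4"]])
  expect_equal(nrow(g34), 12)
  expect_equal(length(unique(round(g34$x, 9))), 4)
  expect_equal(length(unique(round(g34$y, 9))), 3)

  g34r <- generate_layout(lay[["3x4+II"]])
  expect_equal(nrow(g34r), 13)
  expect_equal(sum(g34r$lead == "II"), 2)
  expect_true(all(g34r$x >= 0 & g34r$x <= 1 & g34r$y >= 0 & g34r$y <= 1))
  expect_error(generate_layout("unknown"), "unknown layout")
})

test_that("markers are detected near their rendered labels", {
  rs <- fix_render()
  tprobs <- one_hot_text(rs$lead_text_mask)
  mk <- detect_markers(tprobs)
  expect_equal(sort(unique(mk$lead)), sort(LEAD_NAMES))
  expect_equal(nrow(mk), 13) # rhythm II yields a second, distant marker
  # each marker within one text height of its label box
  fscale <- max(1L, round(0.4 * rs$calibration_truth))
  text_h <- 7 * fscale
  for (i in seq_len(nrow(mk))) {
    ci <- match(mk$lead[i], LEAD_NAMES)
    idx <- which(rs$lead_text_mask == ci)
    rows <- (idx - 1) %% nrow(rs$lead_text_mask)
    cols <- (idx - 1) %/% nrow(rs$lead_text_mask)
    d <- sqrt((cols - mk$x[i])^2 + (rows - mk$y[i])^2)
    expect_lt(min(d), text_h, label = paste("marker", mk$lead[i]))
  }
})

test_that("marker detection handles empty maps and duplicate blobs", {
  empty <- array(0, c(40, 40, 13))
  empty[, , 1] <- 1
  mk <- detect_markers(empty)
  expect_equal(nrow(mk), 0)

  # two nearby blobs for one lead (fragments of one label) merge into a
  # single marker at the larger blob's centroid
  probs <- array(0, c(400, 400, 13))
  probs[10:13, 10:15, 2] <- 0.9 # small blob of lead I
  probs[10:16, 20:28, 2] <- 0.9 # larger blob, nearby
  probs[, , 1] <- 1 - probs[, , 2]
  mk <- detect_markers(probs, min_mass = 2)
  expect_equal(nrow(mk), 1)
  expect_equal(mk$lead, "I")
  expect_equal(mk$x, mean(19:27), tolerance = 1e-6) # larger blob, 0-based
  expect_equal(mk$y, mean(9:15), tolerance = 1e-6)
})

test_that("a perfect marker set selects its template at zero cost", {
  lay <- load_layouts()
  for (nm in names(lay)) {
    mk <- make_marker_set(lay[[nm]], jitter = 0, drop_n = 0, seed = 1)
    ml <- match_layout(mk, lay)
    expect_equal(ml$template$name, nm)
    expect_lt(ml$cost, 1e-9)
  }
})

test_that("one missing marker costs exactly lambda over the template size", {
  lay <- load_layouts()
  tmpl <- lay[["3x4"]]
  mk <- make_marker_set(tmpl, jitter = 0, drop_n = 0, seed = 2)
  mk1 <- mk[-5, ]
  attributes(mk1)[c("width", "height")] <- attributes(mk)[c("width", "height")]
  ml <- match_layout(mk1, lay["3x4"])
  expect_equal(ml$cost, 0.5 / 12, tolerance = 1e-9)
  # the lambda penalty never makes the true template cheaper
  ml_full <- match_layout(mk, lay["3x4"])
  expect_gte(ml$cost, ml_full$cost)
})

test_that("reported costs equal an independent brute-force evaluation", {
  lay <- load_layouts()
  # independent reimplementation of the scoring rule using lm() fits
  oracle_cost <- function(markers, template, lambda = 0.5) {
    g <- generate_layout(template)
    w <- attr(markers, "width"); h <- attr(markers, "height")
    pn <- cbind(markers$x / w, markers$y / h)
    pairs <- NULL
    used_t <- rep(FALSE, nrow(g)); used_d <- rep(FALSE, nrow(markers))
    for (lead in unique(g$lead)) {
      di <- which(markers$lead == lead); ti <- which(g$lead == lead)
      while (length(di) && length(ti)) {
        dm <- outer(di, ti, function(a, b) {
          sqrt((pn[a, 1] - g$x[b])^2 + (pn[a, 2] - g$y[b])^2)
        })
        best <- arrayInd(which.min(dm), dim(dm))
        pairs <- rbind(pairs, c(di[best[1]], ti[best[2]]))
        used_d[di[best[1]]] <- TRUE; used_t[ti[best[2]]] <- TRUE
        di <- di[-best[1]]; ti <- ti[-best[2]]
      }
    }
    if (is.null(pairs)) return(Inf)
    px <- pn[pairs[, 1], 1]; py <- pn[pairs[, 1], 2]
    gx <- g$x[pairs[, 2]]; gy <- g$y[pairs[, 2]]
    fx <- if (length(unique(px)) > 1) coef(lm(gx ~ px)) else c(mean(gx) - mean(px), 1)
    fy <- if (length(unique(py)) > 1) coef(lm(gy ~ py)) else c(mean(gy) - mean(py), 1)
    dx <- fx[1] + fx[2] * px - gx
    dy <- fy[1] + fy[2] * py - gy
    (lambda * (sum(!used_t) + sum(!used_d)) + sum(sqrt(dx^2 + dy^2))) /
      nrow(g)
  }
  for (seed in 1:20) {
    tmpl <- lay[[1 + seed %% 4]]
    mk <- make_marker_set(tmpl, jitter = 0.005, drop_n = seed %% 3,
                          seed = 100 + seed)
    ml <- match_layout(mk, lay)
    for (j in seq_along(lay)) {
      expect_equal(unname(ml$costs[j]), oracle_cost(mk, lay[[j]]),
                   tolerance = 1e-6,
                   label = sprintf("seed %d template %s", seed, names(lay)[j]))
    }
  }
})

test_that("the true layout is selected in at least 95 percent of jittered cases", {
  lay <- load_layouts()
  hits <- 0
  n <- 100
  for (i in seq_len(n)) {
    tmpl <- lay[[1 + i %% 4]]
    mk <- make_marker_set(tmpl, jitter = 0.01, drop_n = i %% 3,
                          seed = 500 + i)
    ml <- suppressWarnings(match_layout(mk, lay))
    if (ml$template$name == tmpl$name) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("cost is invariant to global scale and translation of markers", {
  lay <- load_layouts()
  mk <- make_marker_set(lay[["6x2"]], jitter = 0.008, drop_n = 1, seed = 9)
  ml1 <- match_layout(mk, lay)
  mk2 <- mk
  mk2$x <- mk2$x * 0.6 + 40
  mk2$y <- mk2$y * 1.3 - 10
  attributes(mk2)[c("width", "height")] <- attributes(mk)[c("width", "height")]
  ml2 <- match_layout(mk2, lay)
  expect_equal(ml1$costs, ml2$costs, tolerance = 1e-6)
  expect_equal(ml1$template$name, ml2$template$name)
})

test_that("an unmatchable marker set falls back to the default layout", {
  df <- data.frame(lead = character(), x = numeric(), y = numeric(),
                   mass = numeric(), stringsAsFactors = FALSE)
  mk <- structure(df, width = 100, height = 100,
                  class = c("marker_set", "data.frame"))
  expect_warning(ml <- match_layout(mk), "falling back")
  expect_equal(ml$template$name, "3x4+II")
  expect_true(ml$fallback)
})
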