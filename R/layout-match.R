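# Layout identification: locate lead-name markers from the 13-class text
# segmentation, then pick the candidate template whose marker arrangement
# explains the detections at least cost under a per-axis scale+translation
# fit.

#' Detect lead-name markers from text probabilities
#'
#' For each lead class the probability plane is thresholded, connected blobs
#' below a minimum mass are discarded, and nearby blobs (fragments of the
#' same printed label) are merged; the marker position is the
#' probability-weighted centroid of the heaviest blob of its cluster.
#' Spatially distant repeats of the same lead name (e.g. a rhythm-strip
#' label) yield separate markers.
#'
#' @param text_prob Either an H x W single-channel text-probability matrix
#'   (requires `text_model`), an H x W x 13 probability array as produced
#'   by [segment()] with the lead-text network, or a list with `label`
#'   (0 = background, 1..12 = lead index) and `conf` planes.
#' @param text_model Optional `unet_model` applied to `text_prob`.
#' @param threshold Probability threshold for blob extraction.
#' @param min_mass Minimum blob probability mass.
#' @param merge_frac Blobs of one lead closer than `merge_frac * max(H, W)`
#'   are treated as fragments of the same label.
#' @return A `marker_set`: data frame with columns `lead`, `x`, `y` (0-based
#'   pixel coordinates), `mass`; attributes `width`/`height`.
#' @export
detect_markers <- function(text_prob, text_model = NULL, threshold = 0.5,
                           min_mass = 5, merge_frac = 0.05) {
  if (is.list(text_prob) && !is.null(text_prob$label)) {
    tp_label <- text_prob$label; tp_conf <- text_prob$conf
    h <- nrow(tp_label); w <- ncol(tp_label)
    lead_plane <- function(ci) {
      plane <- matrix(0, h, w)
      sel <- tp_label == ci
      plane[sel] <- tp_conf[sel]
      plane
    }
  } else {
    if (length(dim(text_prob)) == 2L) {
      if (is.null(text_model)) stop("text_model required for single-channel input")
      probs <- segment(text_model, text_prob)
    } else {
      probs <- text_prob
    }
    h <- dim(probs)[1]; w <- dim(probs)[2]
    lead_plane <- function(ci) probs[, , ci + 1]
  }
  radius <- merge_frac * max(h, w)
  out <- list()
  for (ci in 1:12) {
    plane <- lead_plane(ci)
    mask <- plane > threshold
    if (!any(mask)) next
    lab <- label_components8(mask)
    blobs <- list()
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      mass <- sum(plane[idx])
      if (mass < min_mass) next
      rows <- (idx - 1) %% h
      cols <- (idx - 1) %/% h
      wts <- plane[idx] / mass
      blobs[[length(blobs) + 1]] <- list(x = sum(cols * wts),
                                         y = sum(rows * wts), mass = mass)
    }
    if (!length(blobs)) next
    # cluster blobs by proximity; keep the heaviest blob's centroid per
    # cluster, accumulate the cluster mass
    ord <- order(-vapply(blobs, function(b) b$mass, 0))
    clusters <- list()
    for (b in blobs[ord]) {
      placed <- FALSE
      for (j in seq_along(clusters)) {
        cj <- clusters[[j]]
        if (sqrt((b$x - cj$x)^2 + (b$y - cj$y)^2) <= radius) {
          clusters[[j]]$mass <- cj$mass + b$mass # centroid stays: heavier blob
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1]] <- b
    }
    for (cl in clusters) {
      out[[length(out) + 1]] <- data.frame(lead = LEAD_NAMES[ci], x = cl$x,
                                           y = cl$y, mass = cl$mass,
                                           stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(lead = character(), x = numeric(), y = numeric(),
               mass = numeric(), stringsAsFactors = FALSE)
  }
  structure(df, width = w, height = h, class = c("marker_set", "data.frame"))
}

# least-squares per-axis scale + translation mapping detected (normalized)
# positions onto template positions; scale needs >= 2 distinct coordinates
fit_axis_transform <- function(p, g) {
  fit1 <- function(x, t) {
    if (length(x) >= 2 && diff(range(x)) > 1e-9) {
      a <- sum((x - mean(x)) * (t - mean(t))) / sum((x - mean(x))^2)
      c(a, mean(t) - a * mean(x))
    } else {
      c(1, mean(t) - mean(x))
    }
  }
  list(x = fit1(p[, 1], g[, 1]), y = fit1(p[, 2], g[, 2]))
}

apply_axis_transform <- function(tr, p) {
  cbind(tr$x[1] * p[, 1] + tr$x[2], tr$y[1] * p[, 2] + tr$y[2])
}

#' Select the best-matching lead layout
#'
#' Every candidate template is scored by pairing detected markers with
#' template markers of the same lead identity, fitting an independent
#' per-axis scale and translation on the matched pairs, and evaluating
#'
#' `cost = (lambda * (n_missing + n_extra) + sum(distances)) / n_template`
#'
#' where distances are Euclidean in template coordinates and `lambda = 0.5`
#' corresponds to half the image width. Template markers without a matching
#' detection count as missing; detected markers not used by the template
#' count as extra (this separates layouts that differ only by a rhythm
#' strip). The lowest-cost template wins; ties keep candidate order.
#'
#' @param markers A `marker_set` from [detect_markers()].
#' @param candidates List of `layout_template`s (default: bundled registry).
#' @param lambda Penalty per missing/extra marker (default 0.5).
#' @param default Template name used when no candidate matches at all.
#' @return A `layout_match`: list with `template`, `cost`, `matched` (data
#'   frame), `missing`, `extra`, `transform`, and `costs` for all
#'   candidates. Falls back to `default` with a warning when nothing
#'   matches.
#' @export
match_layout <- function(markers, candidates = NULL, lambda = 0.5,
                         default = "3x4+II") {
  candidates <- candidates %||% load_layouts()
  w <- attr(markers, "width"); h <- attr(markers, "height")
  p_norm <- if (nrow(markers)) {
    cbind(markers$x / w, markers$y / h)
  } else {
    matrix(0, 0, 2)
  }
  results <- lapply(candidates, function(tmpl) {
    g <- generate_layout(tmpl)
    pairs <- list() # det index -> template index
    used_det <- rep(FALSE, nrow(markers))
    used_tpl <- rep(FALSE, nrow(g))
    for (lead in unique(g$lead)) {
      di <- which(markers$lead == lead)
      ti <- which(g$lead == lead)
      if (!length(di)) next
      # small exhaustive assignment by raw distance (multiplicity <= 2-3)
      if (length(di) == 1 && length(ti) == 1) {
        pairs[[length(pairs) + 1]] <- c(di, ti)
        used_det[di] <- TRUE; used_tpl[ti] <- TRUE
      } else {
        nd <- length(di); nt <- length(ti)
        k <- min(nd, nt)
        dmat <- outer(seq_len(nd), seq_len(nt), function(a, b) {
          sqrt((p_norm[di[a], 1] - g$x[ti[b]])^2 +
                 (p_norm[di[a], 2] - g$y[ti[b]])^2)
        })
        for (r in seq_len(k)) {
          idx <- arrayInd(which.min(dmat), dim(dmat))
          pairs[[length(pairs) + 1]] <- c(di[idx[1]], ti[idx[2]])
          used_det[di[idx[1]]] <- TRUE; used_tpl[ti[idx[2]]] <- TRUE
          dmat[idx[1], ] <- Inf; dmat[, idx[2]] <- Inf
        }
      }
    }
    n_g <- nrow(g)
    if (!length(pairs)) {
      return(list(cost = Inf, template = tmpl, matched = NULL,
                  missing = g$lead, extra = markers$lead, transform = NULL))
    }
    pm <- do.call(rbind, pairs)
    p_sub <- p_norm[pm[, 1], , drop = FALSE]
    g_sub <- cbind(g$x[pm[, 2]], g$y[pm[, 2]])
    tr <- fit_axis_transform(p_sub, g_sub)
    p_fit <- apply_axis_transform(tr, p_sub)
    dists <- sqrt(rowSums((p_fit - g_sub)^2))
    n_miss <- sum(!used_tpl)
    n_extra <- sum(!used_det)
    cost <- (lambda * (n_miss + n_extra) + sum(dists)) / n_g
    list(cost = cost, template = tmpl,
         matched = data.frame(lead = markers$lead[pm[, 1]],
                              det = pm[, 1], tpl = pm[, 2], dist = dists,
                              stringsAsFactors = FALSE),
         missing = g$lead[!used_tpl],
         extra = markers$lead[!used_det], transform = tr)
  })
  costs <- vapply(results, function(r) r$cost, 0)
  if (all(!is.finite(costs))) {
    warning("no candidate layout matched any marker; falling back to ", default)
    tmpl <- resolve_template(default, candidates)
    return(structure(list(template = tmpl, cost = Inf, matched = NULL,
                          missing = tmpl$panels$lead, extra = character(),
                          transform = NULL, costs = costs, fallback = TRUE),
                     class = "layout_match"))
  }
  best <- which.min(costs)
  structure(c(results[[best]][c("template", "cost", "matched", "missing",
                                "extra", "transform")],
              list(costs = costs, fallback = FALSE)),
            class = "layout_match")
}

#' @export
print.layout_match <- function(x, ...) {
  cat(sprintf("<layout_match> %s (cost %.4f%s)\n", x$template$name, x$cost,
              if (isTRUE(x$fallback)) ", fallback" else ""))
  invisible(x)
}
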