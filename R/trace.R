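# Conversion of the dewarped signal-probability map into per-lead traces:
# 8-connected components, snipping of merged components along
# least-resistance paths, chaining of fragments by minimum-cost assignment,
# and column-wise aggregation into a 1D trace.

#' Extract connected trace components from a signal map
#'
#' @param signal_map Dewarped signal-class probability matrix.
#' @param threshold Binarization threshold (default 0.5).
#' @param min_mass Components with less probability mass are discarded as
#'   specks (default 10).
#' @return List of `trace_component`s: `rows`/`cols` (1-based pixel
#'   indices), `c_min`/`c_max` (column extent), `left_row`/`right_row`
#'   (mean pixel row at the extreme columns), `mass`.
#' @export
extract_components <- function(signal_map, threshold = 0.5, min_mass = 10) {
  mask <- signal_map >= threshold
  if (!any(mask)) return(list())
  lab <- label_components8(mask)
  h <- nrow(signal_map)
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    mass <- sum(signal_map[idx])
    if (mass < min_mass) next
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    c_min <- min(cols); c_max <- max(cols)
    out[[length(out) + 1]] <- structure(
      list(rows = rows, cols = cols, c_min = c_min, c_max = c_max,
           left_row = mean(rows[cols == c_min]),
           right_row = mean(rows[cols == c_max]), mass = mass),
      class = "trace_component")
  }
  out
}

#' Test whether a component likely contains several merged leads
#'
#' A component is flagged when its row extent exceeds one layout lead band,
#' or when more than 20 percent of its columns contain two or more disjoint
#' vertical pixel runs.
#'
#' @param component A `trace_component`.
#' @param band_height Lead band height in pixels.
#' @param multi_run_frac Column fraction threshold (default 0.2).
#' @return Logical.
#' @export
is_problematic <- function(component, band_height, multi_run_frac = 0.2) {
  if (diff(range(component$rows)) > band_height) return(TRUE)
  runs_per_col <- vapply(split(component$rows, component$cols), function(r) {
    r <- sort(r)
    1L + sum(diff(r) > 1L)
  }, 1L)
  mean(runs_per_col >= 2L) > multi_run_frac
}

#' Snip a merged component along a least-resistance path
#'
#' Draws a left-to-right path across the component's column span that
#' minimizes accumulated signal probability, using a greedy one-step
#' lookahead over the moves right, right-up, right-down, up and down
#' (consecutive vertical moves are budgeted to enforce monotone column
#' progress). Path pixels are removed from the component, which is then
#' relabelled.
#'
#' @param component A `trace_component`.
#' @param signal_map The signal probability map the component came from.
#' @param vert_budget Maximum consecutive vertical moves (default 20).
#' @return List of `trace_component`s (the input component unchanged, with
#'   attribute `snip_failed`, when no separating path exists).
#' @export
snip_component <- function(component, signal_map, vert_budget = 20) {
  # the path is confined to the component's exact row extent: a wider
  # corridor would always offer a free path that separates nothing
  h <- nrow(signal_map)
  r0 <- min(component$rows)
  r1 <- max(component$rows)
  c0 <- component$c_min; c1 <- component$c_max
  # a component that fills its bounding box has no separating path: any cut
  # just carves slabs off a solid block
  if (length(component$rows) >= 0.95 * (r1 - r0 + 1) * (c1 - c0 + 1)) {
    attr(component, "snip_failed") <- TRUE
    return(list(component))
  }
  # local cost map: signal probability inside the bounding box
  cost <- signal_map[r0:r1, c0:c1, drop = FALSE]
  nr <- nrow(cost); nc <- ncol(cost)
  at <- function(r, c) if (r < 1 || r > nr || c > nc) Inf else cost[r, c]
  start <- which.min(cost[, 1])
  path <- matrix(NA_integer_, 2L * ((vert_budget + 2L) * nc + nr + 2L), 2)
  n_path <- 0L
  r <- start; c <- 1L
  vert_run <- 0L
  last_vert <- 0L
  while (c <= nc) {
    n_path <- n_path + 1L
    path[n_path, ] <- c(r, c)
    if (c == nc) break
    moves <- list(R = c(0L, 1L), RU = c(-1L, 1L), RD = c(1L, 1L),
                  U = c(-1L, 0L), D = c(1L, 0L))
    if (vert_run >= vert_budget) moves <- moves[1:3]
    if (last_vert == 1L) moves$U <- NULL   # just moved down: no reversal
    if (last_vert == -1L) moves$D <- NULL  # just moved up: no reversal
    best_m <- NULL; best_s <- Inf
    for (mn in names(moves)) {
      mv <- moves[[mn]]
      rr <- r + mv[1]; cc <- c + mv[2]
      if (rr < 1 || rr > nr || cc > nc) next
      s1 <- at(rr, cc)
      # one-step lookahead: cheapest continuation
      s2 <- min(at(rr, cc + 1L), at(rr - 1L, cc + 1L), at(rr + 1L, cc + 1L),
                at(rr - 1L, cc), at(rr + 1L, cc))
      s <- s1 + (if (is.finite(s2)) s2 else 0)
      if (s < best_s - 1e-12) {
        best_s <- s; best_m <- mv
      } else if (is.null(best_m)) {
        best_m <- mv
      }
    }
    if (best_m[2] == 0L) {
      vert_run <- vert_run + 1L
      last_vert <- best_m[1]
    } else {
      vert_run <- 0L
      last_vert <- 0L
    }
    if (best_m[1] != 0L && best_m[2] != 0L) {
      # diagonal move: record the intermediate pixel so the removed path is
      # 4-connected and actually severs 8-connected components
      n_path <- n_path + 1L
      path[n_path, ] <- c(r, c + 1L)
    }
    r <- r + best_m[1]; c <- c + best_m[2]
  }
  path <- path[seq_len(n_path), , drop = FALSE]
  comp_keys <- component$rows + component$cols * (h + 1)

  try_cut <- function(path_local) {
    keep <- rep(TRUE, length(component$rows))
    path_keys <- (path_local[, 1] + r0 - 1L) +
      (path_local[, 2] + c0 - 1L) * (h + 1)
    keep[comp_keys %in% path_keys] <- FALSE
    if (all(keep)) return(NULL)
    sub <- matrix(0, nr, nc)
    sub[cbind(component$rows[keep] - r0 + 1L,
              component$cols[keep] - c0 + 1L)] <-
      signal_map[cbind(component$rows[keep], component$cols[keep])]
    parts <- extract_components(sub, threshold = 1e-9, min_mass = 0)
    if (length(parts) < 2) return(NULL)
    lapply(parts, function(p) {
      p$rows <- p$rows + r0 - 1L
      p$cols <- p$cols + c0 - 1L
      p$c_min <- p$c_min + c0 - 1L
      p$c_max <- p$c_max + c0 - 1L
      p
    })
  }

  parts <- try_cut(path)
  if (is.null(parts) && nr > 2) {
    # the greedy path can cross at a corner that leaves a diagonal link;
    # fall back to a straight cut along the interior row of least ink
    sums <- rowSums(cost)
    k <- which.min(sums[-c(1, nr)]) + 1L
    parts <- try_cut(cbind(k, seq_len(nc)))
  }
  if (is.null(parts)) {
    attr(component, "snip_failed") <- TRUE
    return(list(component))
  }
  parts
}

#' Chain trace components by minimum-cost assignment
#'
#' Right endpoints are matched to left endpoints by solving a linear sum
#' assignment (Jonker-Volgenant). Plausible continuations (the next
#' component starting within `max_back` columns of the previous one's end)
#' cost their weighted Manhattan endpoint distance
#' `|dcol| + w_row * |drow|`, doubled when the connection runs backward in
#' time; strongly backward connections -- including a component wrapping
#' onto itself -- carry the constant `wrap_cost`. The optimal permutation
#' decomposes into cycles; each cycle's most expensive edge is the
#' wrap-around and is dropped, opening the cycle into a chain. Components
#' matched to themselves (singleton cycles) are rejected as noise.
#'
#' @param components List of `trace_component`s.
#' @param w_row Row-distance weight (default 2).
#' @param wrap_cost Constant cost of wrap-around edges; defaults to
#'   `max(100, w_row * (row span of the components))`, which makes long
#'   chains cheaper than fragmenting while keeping distant outliers in
#'   their own (rejected) cycles.
#' @param max_back Largest backward column overlap still treated as a local
#'   (doubled-cost) connection rather than a wrap; defaults to half the
#'   row span.
#' @return List of chains, each an ordered list of components (by column).
#' @export
merge_components <- function(components, w_row = 2, wrap_cost = NULL,
                             max_back = NULL) {
  n <- length(components)
  if (n == 0) return(list())
  if (n == 1) return(list(components))
  cmin <- vapply(components, function(x) x$c_min, 0)
  cmax <- vapply(components, function(x) x$c_max, 0)
  lrow <- vapply(components, function(x) x$left_row, 0)
  rrow <- vapply(components, function(x) x$right_row, 0)
  span_r <- diff(range(unlist(lapply(components, function(x) range(x$rows))))) + 1
  wrap_cost <- wrap_cost %||% max(100, w_row * span_r)
  max_back <- max_back %||% max(20, span_r / 2)
  cost <- outer(seq_len(n), seq_len(n), function(i, j) {
    dx <- cmin[j] - cmax[i]
    base <- abs(dx) + w_row * abs(lrow[j] - rrow[i])
    ifelse(dx < -max_back | i == j, wrap_cost,
           ifelse(dx <= 0, base * 2, base))
  })
  succ <- jv_assign(cost)
  visited <- rep(FALSE, n)
  chains <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    cyc <- s
    k <- succ[s]
    while (k != s) {
      cyc <- c(cyc, k)
      k <- succ[k]
    }
    visited[cyc] <- TRUE
    if (length(cyc) == 1) next # self-connection: noise
    edge_cost <- vapply(seq_along(cyc), function(ii) {
      cost[cyc[ii], succ[cyc[ii]]]
    }, 0)
    drop_i <- which.max(edge_cost)
    start <- succ[cyc[drop_i]]
    chain <- start
    k <- succ[start]
    while (k != start && length(chain) < length(cyc)) {
      chain <- c(chain, k)
      k <- succ[k]
    }
    chains[[length(chains) + 1]] <- components[chain]
  }
  # order chains and their members by column
  chains <- lapply(chains, function(ch) ch[order(vapply(ch, function(x) x$c_min, 0))])
  chains[order(vapply(chains, function(ch) ch[[1]]$c_min, 0))]
}

#' Iteratively extract chains from a signal band
#'
#' Runs component detection, snips problematic components, and re-merges
#' until convergence or the iteration budget is exhausted.
#'
#' @param signal_map Signal probability matrix (one band/strip).
#' @param band_height Expected single-lead band height in pixels.
#' @param threshold,min_mass See [extract_components()].
#' @param max_iter Snip-merge iteration budget (default 10).
#' @param w_row See [merge_components()].
#' @return List of chains as in [merge_components()].
#' @export
band_chains <- function(signal_map, band_height, threshold = 0.5,
                        min_mass = 10, max_iter = 10, w_row = 2) {
  work <- signal_map
  comps <- extract_components(work, threshold, min_mass)
  for (it in seq_len(max_iter)) {
    bad <- which(vapply(comps, is_problematic, TRUE, band_height = band_height))
    if (!length(bad)) break
    changed <- FALSE
    new_comps <- list()
    for (i in seq_along(comps)) {
      if (i %in% bad) {
        parts <- snip_component(comps[[i]], work)
        if (length(parts) > 1) changed <- TRUE
        new_comps <- c(new_comps, parts)
      } else {
        new_comps <- c(new_comps, list(comps[[i]]))
      }
    }
    comps <- new_comps
    if (!changed) break
  }
  merge_components(comps, w_row)
}

#' Convert a chain of components to a per-column trace
#'
#' A printed trace fills each pixel column with a vertical run connecting
#' the previous sample to the current one, so the waveform sample at a
#' column lies where that column's run meets the next column's run. For
#' every column the trace value is therefore the probability-weighted mean
#' row restricted to the overlap of the column's run with its neighbour's
#' run (falling back to the whole run when they do not overlap); empty
#' columns give NA. Rows are converted to millivolts (up is positive) and
#' the per-lead baseline (median of finite values) is subtracted.
#'
#' @param chain List of `trace_component`s (one chain).
#' @param signal_map Signal probability matrix the components index into.
#' @param calibration A `calibration` (or NULL for pixel units).
#' @param col_range Columns spanned by the band (default: full map width).
#' @return A `lead_trace`: list with `columns`, `px_row` (fractional rows,
#'   NA where missing), `mv` (baseline-centred millivolts) and `n_nan`.
#' @export
chain_to_trace <- function(chain, signal_map, calibration = NULL,
                           col_range = c(1L, ncol(signal_map))) {
  cols_all <- seq.int(col_range[1], col_range[2])
  px_row <- rep(NA_real_, length(cols_all))
  if (length(chain)) {
    rows <- unlist(lapply(chain, function(x) x$rows))
    cols <- unlist(lapply(chain, function(x) x$cols))
    wts <- signal_map[cbind(rows, cols)]
    split_rows <- split(rows, cols)
    split_wts <- split(wts, cols)
    col_ids <- as.integer(names(split_rows))
    lo <- vapply(split_rows, min, 0)
    hi <- vapply(split_rows, max, 0)
    # run overlap with the right neighbour (left neighbour for the last
    # column of a run)
    nxt <- match(col_ids + 1L, col_ids)
    prv <- match(col_ids - 1L, col_ids)
    use <- ifelse(!is.na(nxt), nxt, prv)
    h_map <- nrow(signal_map)
    vals <- vapply(seq_along(col_ids), function(i) {
      o_lo <- lo[i]; o_hi <- hi[i]
      if (!is.na(use[i])) {
        ov_lo <- max(lo[i], lo[use[i]])
        ov_hi <- min(hi[i], hi[use[i]])
        if (ov_lo <= ov_hi) {
          o_lo <- ov_lo; o_hi <- ov_hi
        }
      }
      # include sub-threshold soft mass just outside the run: it carries the
      # subpixel position of the trace centre
      w_lo <- max(1L, o_lo - 2L); w_hi <- min(h_map, o_hi + 2L)
      rr <- w_lo:w_hi
      wt <- signal_map[rr, col_ids[i]]
      if (sum(wt) <= 0) {
        rr <- split_rows[[i]]
        wt <- pmax(split_wts[[i]], 1e-6)
      }
      sum(rr * wt) / sum(wt)
    }, 0)
    pos <- match(col_ids, cols_all)
    ok <- !is.na(pos)
    px_row[pos[ok]] <- vals[ok]
  } else {
    warning("empty chain: all-NA trace")
  }
  mv_per_px <- if (is.null(calibration)) 1 else calibration$mV_per_px
  mv <- -px_row * mv_per_px
  mv <- mv - median(mv, na.rm = TRUE)
  structure(list(columns = cols_all, px_row = px_row, mv = mv,
                 n_nan = sum(is.na(px_row))),
            class = "lead_trace")
}
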