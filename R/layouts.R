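#' Load lead-layout templates from a YAML configuration file
#'
#' Each template describes a printed lead arrangement: a rows x cols grid of
#' panels filled with leads in column-major order, optional rhythm leads
#' printed as full-width strips below the grid, and the recording duration.
#' The bundled file registers the common clinical formats 3x4 (with and
#' without a lead II rhythm strip), 6x2 and 12x1.
#'
#' @param path Path to a YAML file; defaults to the bundled registry.
#' @return Named list of `layout_template` objects.
#' @export
load_layouts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "layouts.yaml", package = "ecgdigitizer")
  }
  if (!file.exists(path)) stop("layout config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$layouts)) stop("layout config must have a top-level 'layouts' list")
  out <- lapply(raw$layouts, function(l) {
    layout_template(name = l$name, rows = l$rows, cols = l$cols,
                    leads = unlist(l$leads), rhythm = unlist(l$rhythm),
                    duration_s = l$duration_s %||% 10)
  })
  names(out) <- vapply(out, function(l) l$name, "")
  out
}

#' Construct a lead-layout template
#'
#' @param name Template identifier.
#' @param rows,cols Panel grid shape.
#' @param leads Lead names filling the grid in column-major order
#'   (`rows * cols` entries, unique, subset of the 12 standard leads).
#' @param rhythm Character vector of rhythm leads (full-width strips below
#'   the grid, in order).
#' @param duration_s Total recording duration covered by one paper.
#' @return A `layout_template` with panel boxes in normalized \[0,1\]^2
#'   coordinates, per-panel time windows, and nominal lead-marker positions.
#' @export
layout_template <- function(name, rows, cols, leads, rhythm = character(),
                            duration_s = 10) {
  if (length(leads) != rows * cols) stop("need rows*cols lead names")
  if (anyDuplicated(leads)) stop("grid lead names must be unique")
  if (!all(c(leads, rhythm) %in% LEAD_NAMES)) stop("unknown lead name")
  n_rhy <- length(rhythm)
  nrt <- rows + n_rhy # total strip rows
  grid <- data.frame(
    lead = leads,
    row = rep(seq_len(rows), cols),
    col = rep(seq_len(cols), each = rows),
    rhythm = FALSE, stringsAsFactors = FALSE
  )
  grid$x0 <- (grid$col - 1) / cols
  grid$x1 <- grid$col / cols
  grid$y0 <- (grid$row - 1) / nrt
  grid$y1 <- grid$row / nrt
  grid$t0 <- (grid$col - 1) * duration_s / cols
  grid$t1 <- grid$col * duration_s / cols
  if (n_rhy > 0) {
    rhy <- data.frame(
      lead = rhythm, row = rows + seq_len(n_rhy), col = 1L, rhythm = TRUE,
      x0 = 0, x1 = 1,
      y0 = (rows + seq_len(n_rhy) - 1) / nrt,
      y1 = (rows + seq_len(n_rhy)) / nrt,
      t0 = 0, t1 = duration_s, stringsAsFactors = FALSE
    )
    panels <- rbind(grid, rhy)
  } else {
    panels <- grid
  }
  structure(list(name = name, rows = rows, cols = cols, leads = leads,
                 rhythm = rhythm, duration_s = duration_s, panels = panels),
            class = "layout_template")
}

#' Nominal lead-marker coordinates of a layout template
#'
#' Returns the deterministic normalized positions of every printed lead-name
#' marker in the template (one per panel; rhythm leads contribute their own
#' marker at the rhythm strip). Markers sit near the top-left corner of their
#' panel.
#'
#' @param template A `layout_template` (or a registered template name).
#' @param layouts Registry used when `template` is given by name.
#' @return Data frame with columns `lead`, `x`, `y` (in \[0,1\]^2) and
#'   `rhythm`.
#' @export
generate_layout <- function(template, layouts = NULL) {
  template <- resolve_template(template, layouts)
  p <- template$panels
  data.frame(lead = p$lead,
             x = p$x0 + 0.05 * (p$x1 - p$x0),
             y = p$y0 + 0.2 * (p$y1 - p$y0),
             rhythm = p$rhythm, stringsAsFactors = FALSE)
}

resolve_template <- function(template, layouts = NULL) {
  if (inherits(template, "layout_template")) return(template)
  layouts <- layouts %||% load_layouts()
  if (!template %in% names(layouts)) {
    stop("unknown layout template: ", template)
  }
  layouts[[template]]
}

#' @export
print.layout_template <- function(x, ...) {
  cat(sprintf("<layout_template> %s: %dx%d grid%s, %g s\n", x$name, x$rows,
              x$cols,
              if (length(x$rhythm)) paste0(" + rhythm ", paste(x$rhythm, collapse = ",")) else "",
              x$duration_s))
  invisible(x)
}
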