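#' Cell-plate conformation topology
#'
#' A conformation is named `VxTxG`: V oblate spheroids (vesicles), T elliptic
#' hyperboloid tubes, and G gaps (fenestrations, the genus of the closed
#' surface). `6x7x2` is six vesicles joined by seven tubes enclosing two gaps.
#' The genus always satisfies the cyclomatic identity
#' `G = T - V + n_components`.
#'
#' Layouts place vesicle centers in the equatorial plane:
#' * `chain` -- collinear, for G = 0 (e.g. `2x1x0`, `5x4x0`, `7x6x0`);
#' * `ring` -- a regular V-gon, for a single cycle with T = V (e.g. `4x4x1`);
#' * `ladder` -- a 2-row grid of fused rings for G >= 2 (e.g. `6x7x2`,
#'   `8x10x3`, `10x13x4`).
#' `layout = "auto"` picks the layout from G.
#'
#' @param spec either a string `"VxTxG"` (lowercase x; optional
#'   `@layout=chain|ring|ladder` suffix and `*k` ensemble multiplier), or the
#'   vesicle count V when `t` and `g` are given.
#' @param t,g tube and gap counts when `spec` is numeric.
#' @param layout one of `"auto"`, `"chain"`, `"ring"`, `"ladder"`.
#' @param copies ensemble multiplier: number of identical disconnected copies.
#' @return An object of class `cp_conformation` with fields `v`, `t`, `g`,
#'   `edges` (2-column matrix over vesicle indices), `layout`, `copies`,
#'   `n_components` (per copy, always 1 for the built-in layouts).
#' @seealso [genus()]
#' @export
#' @examples
#' conformation("2x1x0")
#' conformation("6x7x2")           # ladder of fused rings, genus 2
#' conformation("2x1x0*3")         # ensemble of three dumbbells
#' genus(conformation("10x13x4"))
conformation <- function(spec, t = NULL, g = NULL, layout = "auto", copies = 1L) {
  if (is.character(spec)) {
    parsed <- parse_conformation_string(spec)
    v <- parsed$v; t <- parsed$t; g <- parsed$g
    if (!is.null(parsed$layout)) layout <- parsed$layout
    if (!is.null(parsed$copies)) copies <- parsed$copies
  } else {
    v <- spec
    if (is.null(t) || is.null(g)) {
      abort("Provide `t` and `g` with a numeric vesicle count.",
            class = "cellplate_validation_error")
    }
  }
  v <- as.integer(v); t <- as.integer(t); g <- as.integer(g)
  copies <- as.integer(copies)
  if (anyNA(c(v, t, g, copies)) || v < 1 || t < 0 || g < 0 || copies < 1) {
    abort("Counts must satisfy V >= 1, T >= 0, G >= 0, copies >= 1.",
          class = "cellplate_validation_error")
  }
  layout <- match.arg(layout, c("auto", "chain", "ring", "ladder"))
  if (layout == "auto") {
    layout <- if (g == 0) "chain" else if (g == 1) "ring" else "ladder"
  }

  edges <- switch(
    layout,
    chain = {
      if (t != v - 1L) {
        abort(sprintf("Chain layout needs T = V - 1; got %dx%dx%d.", v, t, g),
              class = "cellplate_spec_error")
      }
      if (v > 1) cbind(seq_len(v - 1L), seq_len(v - 1L) + 1L) else matrix(integer(), 0, 2)
    },
    ring = {
      if (t != v || v < 3) {
        abort(sprintf("Ring layout needs T = V >= 3; got %dx%dx%d.", v, t, g),
              class = "cellplate_spec_error")
      }
      cbind(seq_len(v), c(seq_len(v - 1L) + 1L, 1L))
    },
    ladder = {
      # 2 x k grid: nodes 1..k (row 1), k+1..2k (row 2); rails + k rungs
      if (v %% 2L != 0L || v < 4L) {
        abort(sprintf("Ladder layout needs even V >= 4; got %dx%dx%d.", v, t, g),
              class = "cellplate_spec_error")
      }
      k <- v %/% 2L
      if (t != 3L * k - 2L) {
        abort(sprintf("Ladder layout with V = %d needs T = %d; got T = %d.",
                      v, 3L * k - 2L, t),
              class = "cellplate_spec_error")
      }
      rails <- rbind(cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L),
                     cbind(k + seq_len(k - 1L), k + seq_len(k - 1L) + 1L))
      rungs <- cbind(seq_len(k), k + seq_len(k))
      rbind(rails, rungs)
    }
  )
  edges <- matrix(as.integer(edges), ncol = 2)

  conf <- structure(
    list(v = v, t = t, g = g, edges = edges, layout = layout,
         copies = copies, n_components = n_graph_components(v, edges)),
    class = "cp_conformation"
  )
  gcheck <- genus(conf)
  if (gcheck != g) {
    abort(sprintf(
      "Declared genus G = %d disagrees with T - V + components = %d for %dx%dx%d (%s layout).",
      g, gcheck, v, t, g, layout),
      class = "cellplate_spec_error")
  }
  conf
}

parse_conformation_string <- function(s) {
  s0 <- s
  copies <- NULL
  layout <- NULL
  if (grepl("\\*", s)) {
    parts <- strsplit(s, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("^[0-9]+$", parts[2])) {
      abort(sprintf("Malformed ensemble multiplier in spec '%s'.", s0),
            class = "cellplate_validation_error")
    }
    copies <- as.integer(parts[2]); s <- parts[1]
  }
  if (grepl("@", s)) {
    parts <- strsplit(s, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("^layout=", parts[2])) {
      abort(sprintf("Malformed layout suffix in spec '%s'.", s0),
            class = "cellplate_validation_error")
    }
    layout <- sub("^layout=", "", parts[2]); s <- parts[1]
  }
  if (!grepl("^[0-9]+x[0-9]+x[0-9]+$", s)) {
    abort(sprintf("Conformation spec '%s' is not of the form VxTxG.", s0),
          class = "cellplate_validation_error")
  }
  n <- as.integer(strsplit(s, "x", fixed = TRUE)[[1]])
  list(v = n[1], t = n[2], g = n[3], layout = layout, copies = copies)
}

# Connected components of the vesicle graph via union-find.
n_graph_components <- function(v, edges) {
  parent <- seq_len(v)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(v), find, integer(1))))
}

#' Genus of a conformation
#'
#' Computed from the vesicle-tube graph as the cyclomatic number
#' `T - V + n_components`; for the closed membrane surface this equals the
#' number of fenestrations (per copy).
#'
#' @param conf a [conformation()].
#' @return Integer genus of one copy.
#' @export
genus <- function(conf) {
  stopifnot(inherits(conf, "cp_conformation"))
  conf$t - conf$v + conf$n_components
}

#' @export
print.cp_conformation <- function(x, ...) {
  cat(sprintf("<cp_conformation> %dx%dx%d (%s layout)%s\n", x$v, x$t, x$g,
              x$layout,
              if (x$copies > 1) sprintf(" x %d copies", x$copies) else ""))
  invisible(x)
}

#' @export
format.cp_conformation <- function(x, ...) {
  sprintf("%dx%dx%d", x$v, x$t, x$g)
}

#' @method as_tibble cp_conformation
#' @export
as_tibble.cp_conformation <- function(x, ...) {
  tibble(v = x$v, t = x$t, g = x$g, layout = x$layout, copies = x$copies,
         n_components = x$n_components)
}

#' Serialize a conformation to / from JSON
#'
#' @param conf a [conformation()].
#' @param txt JSON text produced by `conformation_json()`.
#' @return `conformation_json()` returns a JSON string; the inverse returns a
#'   `cp_conformation`.
#' @export
conformation_json <- function(conf) {
  stopifnot(inherits(conf, "cp_conformation"))
  jsonlite::toJSON(
    list(V = conf$v, T = conf$t, G = conf$g,
         edges = conf$edges, layout = conf$layout, copies = conf$copies),
    auto_unbox = TRUE, digits = NA)
}

#' @rdname conformation_json
#' @export
conformation_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  conformation(x$V, x$T, x$G, layout = x$layout,
               copies = if (is.null(x$copies)) 1L else x$copies)
}

# Vesicle center coordinates in the equatorial plane for one copy,
# given center-to-center spacing d (nm). Returns V x 2 matrix.
layout_centers <- function(conf, d) {
  v <- conf$v
  switch(
    conf$layout,
    chain = cbind((seq_len(v) - 1) * d, rep(0, v)),
    ring = {
      r_ring <- d / (2 * sin(pi / v))
      ang <- 2 * pi * (seq_len(v) - 1) / v
      cbind(r_ring * cos(ang), r_ring * sin(ang))
    },
    ladder = {
      k <- v %/% 2L
      rbind(cbind((seq_len(k) - 1) * d, rep(0, k)),
            cbind((seq_len(k) - 1) * d, rep(d, k)))
    }
  )
}
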