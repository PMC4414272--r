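#' Protease-by-substrate cross-reactivity grid
#'
#' Long-format digestion outcomes for every protease/substrate
#' combination at stated over-digestion conditions, plus the designated
#' cognate protease of each substrate (the enzyme the cleavage module was
#' designed for).
#'
#' @param data `data.frame` with columns `protease`, `substrate`,
#'   `enzyme_uM`, `fraction_cleaved`, and optionally `time_min`, `temp_C`.
#' @param cognate Named character vector mapping each substrate label to
#'   its cognate protease label.
#' @return Object of class `crossreact_grid`.
#' @export
crossreact_grid <- function(data, cognate) {
  need <- c("protease", "substrate", "enzyme_uM", "fraction_cleaved")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("data error: grid missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_fraction(data$fraction_cleaved, "fraction_cleaved")
  subs <- unique(data$substrate)
  if (!all(subs %in% names(cognate))) {
    stop(sprintf("data error: substrates without a cognate protease: %s",
                 paste(setdiff(subs, names(cognate)), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(data = data, cognate = cognate[subs]),
            class = "crossreact_grid")
}

#' @export
print.crossreact_grid <- function(x, ...) {
  cat(sprintf("Cross-reactivity grid: %d proteases x %d substrates, %d measurements\n",
              length(unique(x$data$protease)),
              length(unique(x$data$substrate)), nrow(x$data)))
  invisible(x)
}

#' Default cleavage-category thresholds
#'
#' Four-level digestion key: `++` highly efficient cleavage, `+`
#' cleavage, `-` traces cleaved, `--` no cleavage. The cutoffs are not
#' dictated by the assay itself; the defaults reflect gel practice — 0.90
#' for "essentially complete", 0.10 as the clear-band boundary, and 0.01
#' as the Coomassie detection limit for trace bands.
#' @return Named numeric vector `c(high = 0.90, clear = 0.10, trace = 0.01)`.
#' @export
default_class_thresholds <- function() {
  c(high = 0.90, clear = 0.10, trace = 0.01)
}

#' Classify a digestion outcome into the four-level key
#'
#' @param fraction Fraction(s) cleaved, in `[0, 1]`.
#' @param thresholds Named vector as from [default_class_thresholds()];
#'   must satisfy `trace < clear < high`.
#' @return Factor with levels `--`, `-`, `+`, `++` (increasing cleavage).
#' @examples
#' classify_cell(c(1, 0.5, 0.05, 0))
#' @export
classify_cell <- function(fraction, thresholds = default_class_thresholds()) {
  check_fraction(fraction, "fraction")
  th <- thresholds[c("trace", "clear", "high")]
  if (any(is.na(th)) || is.unsorted(th, strictly = TRUE)) {
    stop("domain error: thresholds must satisfy trace < clear < high",
         call. = FALSE)
  }
  cut(fraction, breaks = c(-Inf, th, Inf), right = FALSE,
      labels = c("--", "-", "+", "++"))
}

#' Orthogonality verdicts and maximal mutually-orthogonal sets
#'
#' A protease/substrate pair (P_i, S_i) is orthogonal to (P_j, S_j) iff,
#' at the grid's over-digestion conditions, P_i leaves S_j below the
#' cross-cleavage threshold and P_j leaves S_i below it. Verdicts use
#' each pair's maximum tested enzyme concentration — orthogonality is
#' only claimed when heavy over-digestion still shows no cross-cleavage.
#' Self-pairs are excluded by definition. Maximal mutually-orthogonal
#' sets are the maximal cliques of the orthogonality graph.
#'
#' @param grid A [crossreact_grid()]. Every protease/substrate
#'   combination must have at least one measurement.
#' @param strictness `"none"` (default) demands the `--` category (below
#'   the trace threshold) for cross-cells; `"trace"` tolerates trace
#'   cleavage (below the clear-band threshold).
#' @param thresholds Category thresholds, as for [classify_cell()].
#' @return List with `pairs` (cognate protease/substrate pairs),
#'   `verdicts` (logical matrix, pairs x pairs, `NA` diagonal),
#'   `max_orthogonal_sets` (list of character vectors of pair labels),
#'   and `categories` (the classified grid at max tested concentration).
#' @export
orthogonality_calls <- function(grid, strictness = c("none", "trace"),
                                thresholds = default_class_thresholds()) {
  stopifnot(inherits(grid, "crossreact_grid"))
  strictness <- match.arg(strictness)
  cutoff <- unname(thresholds[[if (strictness == "none") "trace" else "clear"]])

  d <- grid$data
  prots <- unique(d$protease)
  subs <- unique(d$substrate)
  all_combos <- expand.grid(protease = prots, substrate = subs,
                            stringsAsFactors = FALSE)
  have <- paste(d$protease, d$substrate, sep = "\r")
  missing <- all_combos[!paste(all_combos$protease, all_combos$substrate,
                               sep = "\r") %in% have, ]
  if (nrow(missing)) {
    stop(sprintf("incomplete-grid error: missing measurements for: %s",
                 paste(sprintf("(%s, %s)", missing$protease,
                               missing$substrate), collapse = "; ")),
         call. = FALSE)
  }

  # fraction at the maximum tested concentration per combination
  frac_at_max <- function(p, s) {
    rows <- d[d$protease == p & d$substrate == s, ]
    rows$fraction_cleaved[which.max(rows$enzyme_uM)]
  }
  fmat <- outer(prots, subs, Vectorize(frac_at_max))
  dimnames(fmat) <- list(prots, subs)

  cats <- data.frame(all_combos,
                     fraction_cleaved = mapply(frac_at_max,
                                               all_combos$protease,
                                               all_combos$substrate))
  cats$category <- classify_cell(cats$fraction_cleaved, thresholds)

  # cognate pairs present in the grid
  pair_subs <- subs[grid$cognate[subs] %in% prots]
  pairs <- data.frame(protease = unname(grid$cognate[pair_subs]),
                      substrate = pair_subs, stringsAsFactors = FALSE)
  pairs$label <- paste(pairs$protease, pairs$substrate, sep = "/")

  n <- nrow(pairs)
  verdicts <- matrix(NA, n, n, dimnames = list(pairs$label, pairs$label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      verdicts[i, j] <-
        fmat[pairs$protease[i], pairs$substrate[j]] < cutoff &&
        fmat[pairs$protease[j], pairs$substrate[i]] < cutoff
    }
  }

  sets <- list()
  if (n > 0) {
    adj <- verdicts
    adj[is.na(adj)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    sets <- lapply(igraph::max_cliques(g),
                   function(cl) sort(pairs$label[as.integer(cl)]))
    sets <- sets[order(-lengths(sets))]
  }

  list(pairs = pairs, verdicts = verdicts,
       max_orthogonal_sets = sets, categories = cats)
}

#' Render a classified grid as a text matrix
#'
#' @param calls Result of [orthogonality_calls()].
#' @return Character matrix (protease rows, substrate columns) of
#'   `++`/`+`/`-`/`--` categories.
#' @export
category_matrix <- function(calls) {
  cats <- calls$categories
  prots <- unique(cats$protease)
  subs <- unique(cats$substrate)
  m <- matrix("", length(prots), length(subs),
              dimnames = list(prots, subs))
  for (k in seq_len(nrow(cats))) {
    m[cats$protease[k], cats$substrate[k]] <- as.character(cats$category[k])
  }
  m
}
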