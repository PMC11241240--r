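#' Receptor-weighted interaction frequency fingerprints
#'
#' A fingerprint is the set of BW positions that frequently contact bound
#' ligands across a corpus of complexes. Because receptors are represented by
#' very different numbers of structures, the frequency of a site is weighted
#' so that every receptor contributes equally: with R distinct receptors and
#' m_i complexes sharing complex i's receptor,
#' f = (1/R) * sum_i I_i / m_i, where I_i indicates whether any contact at
#' the site survives the chosen score cutoff in complex i. The weighted
#' frequency ranges from 0 (no complex interacts) to 1 (all complexes
#' interact) and reduces to the plain fraction of interacting complexes when
#' every receptor has exactly one complex.
#'
#' @name fingerprints
NULL

#' Weighted interaction frequency at one site
#'
#' @param interacts integer/logical vector: does complex i interact at the
#'   site.
#' @param receptor_id receptor identifier per complex.
#' @return the receptor-weighted frequency in [0, 1].
#' @examples
#' # receptor A: 2 complexes both interacting; receptor B: 1 non-interacting
#' weighted_frequency(c(1, 1, 0), c("A", "A", "B"))  # (1/2 + 1/2 + 0) / 2 = 0.5
#' @export
weighted_frequency <- function(interacts, receptor_id) {
  if (length(interacts) == 0L) stop("no complexes supplied")
  stopifnot(length(interacts) == length(receptor_id))
  m <- table(receptor_id)[receptor_id]
  sum(as.numeric(interacts) / as.numeric(m)) / length(unique(receptor_id))
}

#' Build a frequency table from per-complex contact sets
#'
#' @param contact_sets named list of contacts data.frames (one per complex).
#' @param receptor_ids named or parallel character vector: receptor of each
#'   complex.
#' @param activation_states parallel vector of activation states (used by
#'   \code{state_filter}); defaults to all "unknown".
#' @param score_cutoff interaction-score cutoff applied before counting a
#'   site as interacting (0 = no cutoff).
#' @param state_filter \code{"all"} or a subset of activation states.
#' @return object of class \code{gifp_freq_table}: data.frame (bw_position,
#'   weighted_frequency) sorted by BW order, with attributes n_complexes,
#'   n_receptors, score_cutoff, state_filter.
#' @export
build_frequency_table <- function(contact_sets, receptor_ids,
                                  activation_states = NULL,
                                  score_cutoff = 0, state_filter = "all") {
  stopifnot(length(contact_sets) == length(receptor_ids))
  if (is.null(activation_states)) {
    activation_states <- rep("unknown", length(contact_sets))
  }
  if (!identical(state_filter, "all")) {
    keep <- activation_states %in% state_filter
    if (!any(keep)) stop("state_filter excludes all complexes")
    contact_sets <- contact_sets[keep]
    receptor_ids <- receptor_ids[keep]
  }
  site_sets <- lapply(contact_sets, function(ct) {
    unique(filter_by_score(ct, score_cutoff)$bw_position)
  })
  sites <- bw_sort(unique(unlist(site_sets)))
  freq <- vapply(sites, function(s) {
    weighted_frequency(vapply(site_sets, function(x) s %in% x, TRUE),
                       receptor_ids)
  }, 1.0)
  out <- data.frame(bw_position = sites,
                    weighted_frequency = unname(freq),
                    stringsAsFactors = FALSE)
  structure(out, class = c("gifp_freq_table", "data.frame"),
            n_complexes = length(contact_sets),
            n_receptors = length(unique(receptor_ids)),
            score_cutoff = score_cutoff, state_filter = state_filter)
}

#' Threshold a frequency table into a fingerprint
#'
#' @param table a \code{gifp_freq_table}.
#' @param threshold frequency threshold in (0, 1]; sites with frequency >=
#'   threshold are included. A warning is emitted when the resulting site
#'   count falls outside the conventional 10-15 window.
#' @return object of class \code{gifp_fingerprint}: list(sites, threshold,
#'   score_cutoff, state_filter).
#' @export
select_sites <- function(table, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  sites <- table$bw_position[table$weighted_frequency >= threshold]
  sites <- if (length(sites)) bw_sort(sites) else character(0)
  if (length(sites) < 10L || length(sites) > 15L) {
    warning(sprintf("fingerprint has %d sites (outside the 10-15 window)",
                    length(sites)))
  }
  structure(list(sites = sites, threshold = threshold,
                 score_cutoff = attr(table, "score_cutoff"),
                 state_filter = attr(table, "state_filter")),
            class = "gifp_fingerprint")
}

#' Choose a fingerprint threshold automatically
#'
#' Scans a 0.05 grid over [0.35, 0.60] and returns the largest threshold
#' whose site count lies in [min_sites, max_sites] (a tie-break toward fewer
#' sites). If no grid value qualifies, the value whose count is closest to
#' the interval is returned with a warning (ties to the larger threshold).
#'
#' @param table a \code{gifp_freq_table}.
#' @param min_sites,max_sites target window for the number of sites.
#' @return a threshold on the grid.
#' @export
auto_threshold <- function(table, min_sites = 10L, max_sites = 15L) {
  if (all(table$weighted_frequency <= 0)) stop("all frequencies are zero")
  grid <- seq(0.35, 0.60, by = 0.05)
  counts <- vapply(grid, function(th) sum(table$weighted_frequency >= th), 1L)
  ok <- counts >= min_sites & counts <= max_sites
  if (any(ok)) return(grid[max(which(ok))])
  gap <- ifelse(counts < min_sites, min_sites - counts, counts - max_sites)
  best <- which(gap == min(gap))
  warning(sprintf("no threshold on the grid yields %d-%d sites; closest is %.2f (%d sites)",
                  min_sites, max_sites, grid[max(best)], counts[max(best)]))
  grid[max(best)]
}

#' Write a fingerprint to JSON
#' @param fingerprint a \code{gifp_fingerprint}.
#' @param path output path.
#' @export
write_fingerprint <- function(fingerprint, path) {
  jsonlite::write_json(unclass(fingerprint), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
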