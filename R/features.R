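#' BW-indexed interaction profiles and feature tables
#'
#' An interaction profile summarizes one complex per BW position with five
#' fields: the energy sum of all contacts at the position, and the type and
#' energy of the two most favorable (most negative) contacts. Missing-data
#' semantics are explicit and three-valued: a position absent from the
#' receptor (the helix is too short to reach that generic number) is NA /
#' "NA"; a position present but making no ligand contact is 0 / "None"; a
#' position with a single contact has its second type "None" and second
#' energy 0. The distinction between NA and 0 is preserved through CSV
#' round-trips (numeric NA is an empty cell, categorical NA is the literal
#' string "NA").
#'
#' @name features
NULL

.profile_fields <- c("energy_sum", "type1", "energy1", "type2", "energy2")

# rank contacts: most negative energy first; ties by type priority
# (Covalent > Metal > Ionic > Hbond > Arene > Distance), then atom names
.rank_contacts <- function(ct) {
  ord <- order(ct$energy, match(ct$type, .contact_types),
               ct$residue_atom, ct$ligand_atom)
  ct[ord, , drop = FALSE]
}

#' Extract the interaction profile of one complex
#'
#' @param complex an annotated \code{gifp_complex}.
#' @param contacts contacts from \code{\link{detect_contacts}} for the same
#'   complex.
#' @param registry character vector of BW positions defining the profile
#'   rows; defaults to the positions annotated in the complex. Registry
#'   positions absent from this receptor produce all-NA rows.
#' @return object of class \code{gifp_profile}: data.frame (bw_position,
#'   energy_sum, type1, energy1, type2, energy2) with attributes complex_id,
#'   is_modeled, function_label.
#' @export
extract_profile <- function(complex, contacts, registry = NULL) {
  stopifnot(inherits(complex, "gifp_complex"))
  present <- complex$residues$bw[!is.na(complex$residues$bw)]
  if (is.null(registry)) registry <- present
  registry <- bw_sort(registry)
  if (nrow(contacts) && !all(contacts$bw_position %in% present)) {
    stop("contacts reference BW positions absent from the complex")
  }
  n <- length(registry)
  out <- data.frame(bw_position = registry,
                    energy_sum = rep(NA_real_, n),
                    type1 = rep("NA", n), energy1 = rep(NA_real_, n),
                    type2 = rep("NA", n), energy2 = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  here <- registry %in% present
  out$energy_sum[here] <- 0; out$energy1[here] <- 0; out$energy2[here] <- 0
  out$type1[here] <- "None"; out$type2[here] <- "None"
  if (nrow(contacts)) {
    for (pos in intersect(unique(contacts$bw_position), registry)) {
      ct <- .rank_contacts(contacts[contacts$bw_position == pos, , drop = FALSE])
      i <- match(pos, registry)
      out$energy_sum[i] <- sum(ct$energy)
      out$type1[i] <- ct$type[1]; out$energy1[i] <- ct$energy[1]
      if (nrow(ct) >= 2L) {
        out$type2[i] <- ct$type[2]; out$energy2[i] <- ct$energy[2]
      }
    }
  }
  structure(out, class = c("gifp_profile", "data.frame"),
            complex_id = complex$complex_id,
            is_modeled = complex$is_modeled,
            function_label = complex$function_label)
}

#' Positions retained for classifier features
#'
#' A position is retained when the number of profiles with a non-NA and
#' nonzero energy sum at that position exceeds \code{min_count} (strict
#' inequality by default; set \code{strict = FALSE} for >=).
#'
#' @param profiles list of \code{gifp_profile} objects.
#' @param min_count retention threshold (default 10).
#' @param strict if TRUE (default) require count > min_count, else >=.
#' @return character vector of BW positions in canonical order.
#' @export
retained_positions <- function(profiles, min_count = 10L, strict = TRUE) {
  stopifnot(length(profiles) >= 1L)
  counts <- list()
  for (p in profiles) {
    act <- p$bw_position[!is.na(p$energy_sum) & p$energy_sum != 0]
    for (pos in act) counts[[pos]] <- (counts[[pos]] %||% 0L) + 1L
  }
  n <- unlist(counts)
  if (is.null(n)) return(character(0))
  keep <- if (strict) n > min_count else n >= min_count
  if (!any(keep)) return(character(0))
  bw_sort(names(n)[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a labeled feature table from profiles
#'
#' Column layout is deterministic: complex_id, label, is_modeled, then for
#' each retained position in BW order the five fields
#' \code{<pos>_sum, <pos>_type1, <pos>_e1, <pos>_type2, <pos>_e2}.
#'
#' @param profiles list of \code{gifp_profile} objects.
#' @param positions retained BW positions (see
#'   \code{\link{retained_positions}}).
#' @return object of class \code{gifp_features}: data.frame with attribute
#'   \code{positions}.
#' @export
assemble_feature_table <- function(profiles, positions) {
  positions <- if (length(positions)) bw_sort(positions) else character(0)
  rows <- lapply(profiles, function(p) {
    i <- match(positions, p$bw_position)
    vals <- list(complex_id = attr(p, "complex_id") %||% NA_character_,
                 label = attr(p, "function_label") %||% "unlabeled",
                 is_modeled = as.integer(attr(p, "is_modeled") %||% 0L))
    for (k in seq_along(positions)) {
      pos <- positions[k]; j <- i[k]
      if (is.na(j)) {
        vals[[paste0(pos, "_sum")]] <- NA_real_
        vals[[paste0(pos, "_type1")]] <- "NA"
        vals[[paste0(pos, "_e1")]] <- NA_real_
        vals[[paste0(pos, "_type2")]] <- "NA"
        vals[[paste0(pos, "_e2")]] <- NA_real_
      } else {
        vals[[paste0(pos, "_sum")]] <- p$energy_sum[j]
        vals[[paste0(pos, "_type1")]] <- p$type1[j]
        vals[[paste0(pos, "_e1")]] <- p$energy1[j]
        vals[[paste0(pos, "_type2")]] <- p$type2[j]
        vals[[paste0(pos, "_e2")]] <- p$energy2[j]
      }
    }
    as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gifp_features", "data.frame"),
            positions = positions)
}

#' Per-class summaries of a feature table
#'
#' For each retained position and function label: the NA-excluded mean
#' energy sum, the percentage of complexes possessing the position that
#' interact there (nonzero energy sum), and per-interaction-type percentages
#' (a complex counts for a type when the type appears as its first or second
#' interaction at the position).
#'
#' @param table a \code{gifp_features} table.
#' @return data.frame with columns bw_position, label, n_present,
#'   mean_energy_sum, interaction_pct, and pct_<Type> per interaction type.
#' @export
summarize_by_class <- function(table) {
  positions <- attr(table, "positions")
  labels <- unique(table$label)
  rows <- list()
  for (pos in positions) {
    s <- table[[paste0(pos, "_sum")]]
    t1 <- table[[paste0(pos, "_type1")]]
    t2 <- table[[paste0(pos, "_type2")]]
    for (lb in labels) {
      in_class <- table$label == lb
      present <- in_class & !is.na(s)
      n_present <- sum(present)
      row <- data.frame(bw_position = pos, label = lb, n_present = n_present,
                        mean_energy_sum = if (n_present) mean(s[present]) else NA_real_,
                        interaction_pct = if (n_present)
                          100 * sum(s[present] != 0) / n_present else NA_real_,
                        stringsAsFactors = FALSE)
      for (ty in .contact_types) {
        row[[paste0("pct_", ty)]] <- if (n_present)
          100 * sum((t1[present] == ty) | (t2[present] == ty)) / n_present
        else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Write/read a feature table as CSV
#'
#' Numeric NA is written as an empty cell; categorical NA is the literal
#' string "NA", keeping the absent-position vs no-interaction distinction
#' intact through a round-trip.
#'
#' @param table a \code{gifp_features} table.
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "", colClasses = NA)
  # categorical columns may be all-"NA"; force character
  for (nm in grep("_type[12]$", names(out), value = TRUE)) {
    out[[nm]] <- as.character(out[[nm]])
  }
  out$complex_id <- as.character(out$complex_id)
  positions <- unique(sub("_sum$", "", grep("_sum$", names(out), value = TRUE)))
  structure(out, class = c("gifp_features", "data.frame"),
            positions = if (length(positions)) bw_sort(positions) else character(0))
}
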