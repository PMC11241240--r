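#' Ballesteros-Weinstein generic position utilities
#'
#' BW positions are strings of the form \code{"X.YY"} where \code{X} is the
#' transmembrane helix number (1-7, or 8 for helix 8) or the two-digit code of
#' the loop between two helices (e.g. 45 for ECL2), and \code{YY} is the
#' offset relative to the most conserved residue of that segment, which is
#' assigned 50. Positions are totally ordered by segment (N- to C-terminal
#' along the receptor) and then by offset, so that e.g. 3.32 < 45.52 < 6.55.
#'
#' @name bw
#' @keywords internal
NULL

# canonical N->C segment order: helices interleaved with their loops
.bw_segments <- c("1", "12", "2", "23", "3", "34", "4", "45",
                  "5", "56", "6", "67", "7", "78", "8")

#' Validate and normalize BW position strings
#'
#' @param x character vector such as \code{c("3.32", "45.52")}.
#' @return the input, normalized (no leading zeros in the segment, two-digit
#'   offset preserved as written), with class retained as plain character.
#' @examples
#' bw_position(c("1.50", "45.52"))
#' @export
bw_position <- function(x) {
  x <- as.character(x)
  if (length(x) == 0L) return(character(0))
  m <- regmatches(x, regexec("^([0-9]{1,2})\\.([0-9]{1,2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed BW position(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  seg <- vapply(m, `[`, "", 2L)
  off <- vapply(m, `[`, "", 3L)
  if (any(!seg %in% .bw_segments)) {
    stop("unknown BW segment(s): ",
         paste(unique(seg[!seg %in% .bw_segments]), collapse = ", "))
  }
  offi <- as.integer(off)
  if (any(offi < 1L | offi > 99L)) stop("BW offset out of range 1-99")
  paste0(seg, ".", formatC(offi, width = 2, flag = "0"))
}

#' Rank BW positions in canonical receptor order
#'
#' @param x character vector of BW positions.
#' @return integer sort keys; ties impossible for valid distinct positions.
#' @export
bw_rank <- function(x) {
  x <- bw_position(x)
  seg <- sub("\\..*$", "", x)
  off <- as.integer(sub("^.*\\.", "", x))
  match(seg, .bw_segments) * 100L + off
}

#' Sort BW positions by segment, then offset
#'
#' @param x character vector of BW positions.
#' @return sorted character vector.
#' @examples
#' bw_sort(c("6.55", "3.32", "45.52"))  # "3.32" "45.52" "6.55"
#' @export
bw_sort <- function(x) {
  x <- bw_position(x)
  x[order(bw_rank(x))]
}
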