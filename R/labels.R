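#' The six-class transmitter label space
#'
#' All matrices, score vectors and vote fractions in this package are indexed
#' by the six fast-acting / monoamine transmitter classes in one fixed
#' canonical order. Keeping the order immutable within a run is what makes
#' confusion-matrix rows, score columns and subset enumeration line up.
#'
#' @return Character vector of the six canonical labels, in canonical order:
#'   gaba, acetylcholine, glutamate, serotonin, octopamine, dopamine.
#' @export
#' @examples
#' transmitter_labels()
transmitter_labels <- function() {
  c("gaba", "acetylcholine", "glutamate", "serotonin", "octopamine", "dopamine")
}

# Alias map for common abbreviations and dialect spellings; keys lower-case.
.nt_aliases <- c(
  gaba = "gaba", "γ-aminobutyric acid" = "gaba",
  acetylcholine = "acetylcholine", ach = "acetylcholine", ach. = "acetylcholine",
  glutamate = "glutamate", glut = "glutamate", glu = "glutamate",
  serotonin = "serotonin", "5-ht" = "serotonin", "5ht" = "serotonin",
  ser = "serotonin", sert = "serotonin",
  octopamine = "octopamine", oct = "octopamine", oa = "octopamine",
  dopamine = "dopamine", da = "dopamine", dop = "dopamine",
  uncertain = "uncertain"
)

#' Normalize transmitter labels to the canonical vocabulary
#'
#' Case-insensitive mapping of common abbreviations ("ACh", "5-HT", "Glut",
#' "DA", ...) onto the canonical six labels. The sentinel `"uncertain"` is
#' passed through unchanged; `NA` stays `NA`.
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_transmitters(c("ACh", "GABA", "5-HT"))
normalize_transmitters <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.nt_aliases[key])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unknown transmitter label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out[is.na(x)] <- NA_character_
  out
}

# internal: assert a character vector only contains canonical labels
# (optionally the "uncertain" sentinel)
.check_labels <- function(x, allow_uncertain = FALSE) {
  ok <- transmitter_labels()
  if (allow_uncertain) ok <- c(ok, "uncertain")
  bad <- setdiff(unique(x[!is.na(x)]), ok)
  if (length(bad) > 0) {
    stop("labels outside the canonical vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# internal: names of the per-class score columns in a synapse table
.score_cols <- function() paste0("score_", transmitter_labels())
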