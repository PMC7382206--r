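# Restriction-site scanning and fragment-length computation.
# The bundled catalogue carries the five-enzyme identification panel with
# standard REBASE recognition sequences and top-strand cut offsets
# (Eco147I is an isoschizomer of StuI, XagI of EcoNI, HindII of HincII).

#' Construct a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition pattern.
#' @param cut_offset 0-based index into the recognition site of the first
#'   base of the downstream fragment (top strand); must lie in
#'   \code{[0, nchar(recognition)]}.
#' @return An object of class \code{restriction_enzyme}.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  rec <- .residues(dna_seq(recognition, id = name))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(rec)) {
    stop("cut_offset outside recognition site for ", name)
  }
  structure(
    list(name = name, recognition = rec, cut_offset = cut_offset,
         palindromic = identical(reverse_complement(rec), rec)),
    class = "restriction_enzyme"
  )
}

#' The bundled five-enzyme panel
#'
#' Eco147I (AGG^CCT), HinfI (G^ANTC), MboI (^GATC), XagI (CCTNN^NNNAGG)
#' and HindII (GTY^RAC). All five recognition patterns equal their own
#' IUPAC reverse complement; this is asserted at load (a non-palindromic
#' user-supplied enzyme is handled by additionally scanning with the
#' reverse-complemented pattern).
#'
#' @return Named list of \code{\link{restriction_enzyme}} objects.
#' @export
enzyme_catalogue <- function() {
  cat <- list(
    restriction_enzyme("Eco147I", "AGGCCT", 3),
    restriction_enzyme("HinfI",   "GANTC",  1),
    restriction_enzyme("MboI",    "GATC",   0),
    restriction_enzyme("XagI",    "CCTNNNNNAGG", 5),
    restriction_enzyme("HindII",  "GTYRAC", 3)
  )
  names(cat) <- vapply(cat, `[[`, character(1), "name")
  stopifnot(all(vapply(cat, `[[`, logical(1), "palindromic")))
  cat
}

#' Find recognition-site occurrences
#'
#' Reports every 0-based start position where the pattern matches the
#' sequence base-by-base under \code{\link{iupac_match}} in the given mode.
#' Overlapping occurrences are all reported. In the default subset mode an
#' ambiguous sequence base (e.g. N) does not create a site: an ambiguous
#' base cannot be guaranteed cleavable.
#'
#' @param seq A \code{dna_seq} or residue string.
#' @param enzyme A \code{\link{restriction_enzyme}}, or a raw IUPAC pattern.
#' @param mode \code{"subset"} (default) or \code{"intersect"}.
#' @return Sorted integer vector of 0-based site starts.
#' @export
find_sites <- function(seq, enzyme, mode = c("subset", "intersect")) {
  mode <- match.arg(mode)
  pattern <- if (inherits(enzyme, "restriction_enzyme")) {
    enzyme$recognition
  } else toupper(enzyme)
  sb <- .seq_bits(.residues(seq))
  pb <- .seq_bits(pattern)
  n <- length(sb)
  m <- length(pb)
  if (m > n) return(integer(0))
  k <- n - m + 1L
  ok <- rep(TRUE, k)
  for (j in seq_len(m)) {
    win <- sb[j:(j + k - 1L)]
    ok <- ok & if (mode == "subset") {
      bitwAnd(win, bitwNot(pb[j])) == 0L
    } else {
      bitwAnd(win, pb[j]) != 0L
    }
  }
  which(ok) - 1L
}

# top-strand cut positions for an enzyme; scans the reverse-complement
# pattern too when the recognition sequence is not palindromic
.cut_positions <- function(seq, enzyme, mode = "subset") {
  res <- .residues(seq)
  m <- nchar(enzyme$recognition)
  cuts <- find_sites(res, enzyme, mode) + enzyme$cut_offset
  if (!enzyme$palindromic) {
    rc_sites <- find_sites(res, reverse_complement(enzyme$recognition), mode)
    cuts <- c(cuts, rc_sites + (m - enzyme$cut_offset))
  }
  n <- nchar(res)
  sort(unique(cuts[cuts > 0 & cuts < n]))  # terminal nicks yield no band
}

#' Digest a linear sequence with one enzyme
#'
#' Complete single-enzyme digestion: cut positions are the site starts
#' plus the enzyme's cut offset (duplicates collapsed, terminal positions
#' discarded); fragments are the successive differences along the
#' sequence, 5' to 3'. Zero sites yield the single full-length fragment.
#'
#' @param seq A \code{dna_seq}, \code{amplicon}, or residue string.
#' @param enzyme A \code{\link{restriction_enzyme}}.
#' @return An object of class \code{digest_result}: list with
#'   \code{enzyme}, \code{cut_positions} (0-based) and \code{fragments}
#'   (bp, ordered 5' to 3'; always sums to the sequence length).
#' @examples
#' digest("AAGATCAA", enzyme_catalogue()$MboI)$fragments  # 2, 6
#' @export
digest <- function(seq, enzyme) {
  res <- .residues(seq)
  cuts <- .cut_positions(res, enzyme)
  structure(
    list(enzyme = enzyme$name, cut_positions = cuts,
         fragments = diff(c(0L, cuts, nchar(res)))),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest> %s: %s\n", x$enzyme,
              paste(x$fragments, collapse = ", ")))
  invisible(x)
}

#' Digest with an enzyme panel
#'
#' Runs \code{\link{digest}} independently for each enzyme (single-enzyme
#' reactions, as in the assay: one enzyme per tube) and collects the
#' fragment lists into a \code{\link{fragment_pattern}}.
#'
#' @param seq A \code{dna_seq}, \code{amplicon}, or residue string.
#' @param enzymes Named list of \code{\link{restriction_enzyme}} (default:
#'   the bundled five-enzyme catalogue). Duplicate names are an error.
#' @return A \code{fragment_pattern} with provenance \code{"predicted"}.
#' @export
digest_panel <- function(seq, enzymes = enzyme_catalogue()) {
  if (length(enzymes) == 0) stop("enzyme list is empty")
  nm <- vapply(enzymes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate enzyme names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  frags <- lapply(enzymes, function(e) digest(seq, e)$fragments)
  names(frags) <- nm
  fragment_pattern(frags, provenance = "predicted")
}
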