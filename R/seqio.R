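# Sequence representation, IUPAC semantics, and FASTA I/O.
# Internal currency: `dna_seq`, a light S3 object holding an id, an
# uppercased residue string over the 15-letter IUPAC nucleotide alphabet,
# and an optional free-text description.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# bitmask encoding A=1, C=2, G=4, T=8; a letter's mask is the OR of its set
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
IUPAC_BITS <- vapply(IUPAC_SETS, function(s) sum(.base_bits[s]), integer(1))

.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Construct a nucleotide sequence
#'
#' Creates the package's sequence object: an identifier plus a residue
#' string over the 15-letter IUPAC nucleotide alphabet. Residues are
#' uppercased on ingest and RNA-style \code{U} is mapped to \code{T}.
#' Gap characters (\code{-}, \code{.}) and any other non-IUPAC character
#' are rejected: the toolkit works on ungapped sequences, and silently
#' stripping gaps would shift restriction-cut coordinates.
#'
#' @param residues Character scalar of nucleotide residues.
#' @param id Identifier (free text).
#' @param description Optional free-text description.
#' @return An object of class \code{dna_seq} with elements \code{id},
#'   \code{residues} and \code{description}.
#' @examples
#' dna_seq("acgtu", id = "x")  # -> residues "ACGTT"
#' @export
dna_seq <- function(residues, id = "", description = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  res <- chartr("u", "T", toupper(residues))
  res <- gsub("U", "T", res, fixed = TRUE)
  bad <- which(!strsplit(res, "", fixed = TRUE)[[1]] %in% IUPAC_LETTERS)
  if (length(bad)) {
    stop(sprintf(
      "sequence '%s': non-IUPAC residue '%s' at position %d",
      id, substr(res, bad[1], bad[1]), bad[1]
    ), call. = FALSE)
  }
  structure(
    list(id = as.character(id), residues = res, description = description),
    class = "dna_seq"
  )
}

#' @export
print.dna_seq <- function(x, ...) {
  cat(sprintf("<dna_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

#' @export
as.character.dna_seq <- function(x, ...) x$residues

# residues of a dna_seq or a plain character scalar
.residues <- function(x) {
  if (inherits(x, "dna_seq")) x$residues
  else if (inherits(x, "amplicon")) x$sequence$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a dna_seq, amplicon, or character scalar")
}

.seq_id <- function(x, default = "") {
  if (inherits(x, "dna_seq")) x$id
  else if (inherits(x, "amplicon")) x$sequence$id
  else default
}

# integer bitmask vector for a residue string (validated)
.seq_bits <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bits <- IUPAC_BITS[chars]
  if (anyNA(bits)) {
    stop(sprintf("non-IUPAC residue '%s' at position %d",
                 chars[which(is.na(bits))[1]], which(is.na(bits))[1]),
         call. = FALSE)
  }
  unname(bits)
}

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a list of
#' \code{\link{dna_seq}} objects, preserving record order. Residues are
#' uppercased and \code{U} mapped to \code{T}; gap or non-IUPAC characters
#' raise an error naming the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @return List of \code{dna_seq}. An empty file yields an empty list.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    hdr <- headers[i]
    id <- sub("\\s.*$", "", hdr)
    desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else NULL
    out[[i]] <- tryCatch(
      dna_seq(as.character(set[[i]]), id = id, description = desc),
      error = function(e) stop(sprintf("record %d (%s): %s", i, id,
                                       conditionMessage(e)), call. = FALSE)
    )
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A \code{dna_seq} or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  res <- vapply(seqs, .residues, character(1))
  ids <- vapply(seqs, function(s) {
    if (!is.null(s$description)) paste(s$id, s$description) else s$id
  }, character(1))
  set <- Biostrings::BStringSet(res)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' IUPAC-aware reverse complement
#'
#' Complements every residue under the full IUPAC code (R to Y, S to S,
#' W to W, K to M, B to V, D to H, N to N, ...) and reverses the string.
#' An involution: applying it twice returns the input.
#'
#' @param x A \code{dna_seq} or residue string.
#' @return Same type as the input.
#' @examples
#' reverse_complement("AAR")  # "YTT"
#' @export
reverse_complement <- function(x) {
  res <- .residues(x)
  comp <- chartr(paste(names(.complement_map), collapse = ""),
                 paste(.complement_map, collapse = ""), res)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  if (inherits(x, "dna_seq")) {
    out <- x
    out$residues <- rc
    out
  } else rc
}

#' Compare two IUPAC letters
#'
#' In \code{subset} mode the pair matches when the base set denoted by the
#' subject letter is contained in the set of the pattern letter (a template
#' \code{N} does not satisfy a \code{Y} in a recognition site). In
#' \code{intersect} mode the pair matches when the two sets share at least
#' one base (permissive, used for primer annealing). Vectorized over both
#' arguments with the usual recycling.
#'
#' @param pattern_base,subject_base IUPAC letters (character vectors).
#' @param mode \code{"subset"} or \code{"intersect"}.
#' @return Logical vector.
#' @examples
#' iupac_match("Y", "C", "subset")     # TRUE
#' iupac_match("Y", "N", "subset")     # FALSE
#' iupac_match("Y", "N", "intersect")  # TRUE
#' @export
iupac_match <- function(pattern_base, subject_base,
                        mode = c("subset", "intersect")) {
  mode <- match.arg(mode)
  p <- IUPAC_BITS[toupper(pattern_base)]
  s <- IUPAC_BITS[toupper(subject_base)]
  if (anyNA(p) || anyNA(s)) stop("letters must be IUPAC nucleotide codes")
  if (mode == "subset") bitwAnd(s, bitwNot(p)) == 0L else bitwAnd(s, p) != 0L
}

# random ACGT string, used by fixture construction
.random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run code with the RNG seeded, restoring prior RNG state afterwards so
# generators are pure in (spec, seed) without disturbing the session stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
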