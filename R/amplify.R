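# In-silico PCR: locate the universal Cytb primer pair on a template and
# excise the amplicon. The bundled pair amplifies a 357-bp fragment of the
# mitochondrial cytochrome b gene in tunas and their common substitutes.

#' The bundled Cytb primer pair
#'
#' Universal primers for the tuna Cytb marker: forward Cytb-1
#' (\code{CCATCCAACATCTCAGCATGATGAAA}, 26 nt) and reverse Cytb-2
#' (\code{CCCTCAGAATGATATTTGTCCTCA}, 24 nt), both written 5' to 3'.
#' Together they amplify a 357-bp product from all eight panel species.
#'
#' @param max_mismatches Mismatches tolerated per primer (default 0;
#'   exact matching is the conservative default and the bundled fixtures
#'   are built to match exactly).
#' @param clamp_3prime Number of 3'-terminal primer bases in which no
#'   mismatch is tolerated (default 3); mismatches at the extension end
#'   abolish amplification much more strongly than internal ones.
#' @return An object of class \code{primer_pair}.
#' @export
cytb_primer_pair <- function(max_mismatches = 0, clamp_3prime = 3) {
  primer_pair(
    forward = primer("Cytb-1", "CCATCCAACATCTCAGCATGATGAAA"),
    reverse = primer("Cytb-2", "CCCTCAGAATGATATTTGTCCTCA"),
    max_mismatches = max_mismatches,
    clamp_3prime = clamp_3prime
  )
}

#' Construct a primer
#' @param name Primer name.
#' @param sequence Residues, 5' to 3' (IUPAC letters allowed).
#' @return An object of class \code{primer}.
#' @export
primer <- function(name, sequence) {
  res <- .residues(dna_seq(sequence, id = name))
  if (nchar(res) == 0) stop("primer '", name, "' is empty")
  structure(list(name = name, sequence = res), class = "primer")
}

#' Construct a primer pair
#' @param forward,reverse \code{\link{primer}} objects (or residue strings).
#' @param max_mismatches,clamp_3prime See \code{\link{cytb_primer_pair}}.
#' @return An object of class \code{primer_pair}.
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 0,
                        clamp_3prime = 3) {
  if (!inherits(forward, "primer")) forward <- primer("forward", forward)
  if (!inherits(reverse, "primer")) reverse <- primer("reverse", reverse)
  stopifnot(max_mismatches >= 0, clamp_3prime >= 0)
  if (clamp_3prime > nchar(forward$sequence) ||
      clamp_3prime > nchar(reverse$sequence)) {
    stop("clamp_3prime exceeds a primer length")
  }
  structure(
    list(forward = forward, reverse = reverse,
         max_mismatches = as.integer(max_mismatches),
         clamp_3prime = as.integer(clamp_3prime)),
    class = "primer_pair"
  )
}

# plus-strand scan: mismatch count of `primer_bits` against every window of
# `tmpl_bits`, using intersect-mode matching (a template N never breaks a
# primer hit). Returns data.frame(position, mismatches) with 0-based starts.
.scan_primer <- function(tmpl_bits, primer_bits, max_mismatches,
                         clamp_3prime) {
  n <- length(tmpl_bits)
  m <- length(primer_bits)
  if (m > n) return(data.frame(position = integer(0), mismatches = integer(0)))
  k <- n - m + 1L
  mm <- integer(k)
  clamp_bad <- logical(k)
  for (j in seq_len(m)) {
    hit <- bitwAnd(tmpl_bits[j:(j + k - 1L)], primer_bits[j]) != 0L
    mm <- mm + !hit
    if (j > m - clamp_3prime) clamp_bad <- clamp_bad | !hit
  }
  keep <- mm <= max_mismatches & !clamp_bad
  data.frame(position = which(keep) - 1L, mismatches = mm[keep])
}

#' Find primer binding sites on both strands
#'
#' Scans the template plus strand left-to-right with the primer, and the
#' minus strand by scanning the reverse complement, reporting every window
#' with at most \code{max_mismatches} mismatches and none in the final
#' \code{clamp_3prime} primer bases. Degenerate template bases are compared
#' by intersect-mode \code{\link{iupac_match}}. Positions are 0-based starts
#' of the occupied window on the template plus strand.
#'
#' @param template A \code{dna_seq} or residue string.
#' @param primer A \code{\link{primer}} or residue string.
#' @param max_mismatches,clamp_3prime Match stringency.
#' @return \code{data.frame(position, strand, mismatches)} sorted by
#'   position; empty when the primer is longer than the template.
#' @export
find_primer_sites <- function(template, primer, max_mismatches = 0,
                              clamp_3prime = 3) {
  if (inherits(primer, "primer")) primer <- primer$sequence
  tmpl <- .residues(template)
  tb <- .seq_bits(tmpl)
  pb <- .seq_bits(toupper(primer))
  n <- length(tb)
  m <- length(pb)
  plus <- .scan_primer(tb, pb, max_mismatches, clamp_3prime)
  rb <- .seq_bits(reverse_complement(tmpl))
  minus <- .scan_primer(rb, pb, max_mismatches, clamp_3prime)
  if (nrow(minus)) minus$position <- n - minus$position - m
  out <- rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) cbind(minus, strand = "-") else NULL
  )
  if (is.null(out)) {
    return(data.frame(position = integer(0), mismatches = integer(0),
                      strand = character(0)))
  }
  out[order(out$position, out$strand), c("position", "strand", "mismatches")]
}

.amplicon <- function(sequence, template_id, start, end, strand) {
  structure(
    list(sequence = sequence, template_id = template_id,
         start = as.integer(start), end = as.integer(end), strand = strand),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %d bp from %s [%d, %d) strand %s\n",
              x$end - x$start, x$template_id, x$start, x$end, x$strand))
  invisible(x)
}

#' In-silico PCR amplification
#'
#' Pairs every forward-primer hit with every correctly oriented downstream
#' reverse-primer hit and reports each product whose length falls inside
#' \code{[min_len, max_len]}. Products are reported 5' to 3' from the
#' forward primer; products whose forward primer binds the template minus
#' strand are reverse-complemented into forward orientation, so
#' amplification is invariant under reverse-complementing the template.
#' All products are reported; no "best" product is selected.
#'
#' @param template A \code{dna_seq} or residue string.
#' @param pair A \code{\link{primer_pair}} (default: the bundled Cytb pair).
#' @param min_len,max_len Accepted product length window in bp. The default
#'   \code{[300, 400]} brackets the expected 357-bp Cytb product and rejects
#'   spurious long products.
#' @return List of \code{amplicon} objects (possibly empty). Coordinates are
#'   0-based half-open on the template plus strand; \code{end - start}
#'   always equals the product length.
#' @export
amplify <- function(template, pair = cytb_primer_pair(),
                    min_len = 300, max_len = 400) {
  stopifnot(min_len <= max_len)
  tmpl <- .residues(template)
  tid <- .seq_id(template, "template")
  fw <- find_primer_sites(tmpl, pair$forward, pair$max_mismatches,
                          pair$clamp_3prime)
  rv <- find_primer_sites(tmpl, pair$reverse, pair$max_mismatches,
                          pair$clamp_3prime)
  mf <- nchar(pair$forward$sequence)
  mr <- nchar(pair$reverse$sequence)
  out <- list()
  # forward primer on plus strand, reverse primer on minus strand downstream
  fp <- fw[fw$strand == "+", , drop = FALSE]
  rm_ <- rv[rv$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(fp))) {
    for (j in seq_len(nrow(rm_))) {
      s <- fp$position[i]
      e <- rm_$position[j] + mr
      len <- e - s
      if (rm_$position[j] >= s && len >= min_len && len <= max_len) {
        prod <- substr(tmpl, s + 1, e)
        out[[length(out) + 1L]] <- .amplicon(
          dna_seq(prod, id = sprintf("%s|amplicon:%d-%d(+)", tid, s, e)),
          tid, s, e, "+"
        )
      }
    }
  }
  # forward primer on minus strand, reverse primer on plus strand upstream
  fm <- fw[fw$strand == "-", , drop = FALSE]
  rp <- rv[rv$strand == "+", , drop = FALSE]
  for (i in seq_len(nrow(fm))) {
    for (j in seq_len(nrow(rp))) {
      s <- rp$position[j]
      e <- fm$position[i] + mf
      len <- e - s
      if (fm$position[i] >= s && len >= min_len && len <= max_len) {
        prod <- reverse_complement(substr(tmpl, s + 1, e))
        out[[length(out) + 1L]] <- .amplicon(
          dna_seq(prod, id = sprintf("%s|amplicon:%d-%d(-)", tid, s, e)),
          tid, s, e, "-"
        )
      }
    }
  }
  out
}
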