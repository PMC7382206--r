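# Constructive synthetic-sequence generator. Builds 357-bp amplicons whose
# five-enzyme digests reproduce a reference fingerprint exactly, embeds
# them in random flanks to give the in-silico PCR a nontrivial search
# problem, and assembles the bundled 39-sample commercial cohort.
#
# These fixtures are signature-faithful, not biologically faithful: outside
# the primers and the planted recognition sites the interior is random, so
# they carry a species' diagnostic band pattern without modeling real Cytb
# evolution.

# all permutations of a small vector (listed order first, duplicates removed)
.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  unique(out)
}

# resolve a species argument (binomial, short code, or common name)
.resolve_species <- function(species, panel) {
  if (species %in% names(panel)) return(species)
  meta <- attr(panel, "meta")
  if (!is.null(meta)) {
    hit <- which(tolower(meta$code) == tolower(species) |
                   tolower(meta$common_name) == tolower(species))
    if (length(hit) == 1) return(meta$species[hit])
  }
  stop("unknown panel species: ", species)
}

# Core constructor, no seeding (callers wrap in .with_seed).
# Maintains a per-position set of allowed bases: primer positions are
# fixed, planted recognition-site positions are restricted to the
# pattern letter's IUPAC set (intersected where sites overlap), the rest
# are free ACGT. Every draw from the allowed sets therefore contains all
# planted sites by construction; the verification loop only has to
# eliminate unintended sites by redrawing the free bases they cover.
.build_amplicon_impl <- function(species, target, enzymes, pair, L,
                                 max_attempts = 1000) {
  lens <- vapply(target, sum, integer(1))
  if (any(lens != L)) {
    bad <- names(target)[lens != L][1]
    stop(sprintf(
      "target fragments for %s sum to %d; expected amplicon length %d (fragment conservation)",
      bad, lens[lens != L][1], L))
  }
  fwd <- pair$forward$sequence
  rcr <- reverse_complement(pair$reverse$sequence)
  if (nchar(fwd) + nchar(rcr) > L) stop("primers longer than amplicon")

  allowed <- rep(list(c("A", "C", "G", "T")), L)
  fix <- function(start0, letters) {                # 0-based start
    for (k in seq_along(letters)) {
      i <- start0 + k
      cur <- intersect(allowed[[i]], IUPAC_SETS[[letters[k]]])
      if (length(cur) == 0) return(FALSE)
      allowed[[i]] <<- cur
    }
    TRUE
  }
  stopifnot(fix(0L, strsplit(fwd, "")[[1]]))
  stopifnot(fix(L - nchar(rcr), strsplit(rcr, "")[[1]]))

  # plant cut sites enzyme by enzyme; fall back to another fragment order
  # when the listed order makes site windows collide (matching downstream
  # is order-free, so any order reproduces the reference multiset)
  expected <- stats::setNames(rep(list(integer(0)), length(enzymes)),
                              names(enzymes))
  planted <- list()
  for (ename in intersect(names(enzymes), names(target))) {
    frags <- target[[ename]]
    if (length(frags) < 2) next
    enz <- enzymes[[ename]]
    pat <- strsplit(enz$recognition, "")[[1]]
    m <- length(pat)
    done <- FALSE
    for (ord in .permutations(frags)) {
      cuts <- cumsum(ord)[-length(ord)]
      starts <- cuts - enz$cut_offset
      if (any(starts < 0 | starts + m > L)) next
      snapshot <- allowed
      ok <- all(vapply(starts, function(s) fix(s, pat), logical(1)))
      if (ok) {
        expected[[ename]] <- sort(cuts)
        planted[[ename]] <- starts
        done <- TRUE
        break
      }
      allowed <- snapshot
    }
    if (!done) {
      stop(sprintf(
        "cannot place %s sites for %s: every fragment order collides with previously planted constraints",
        ename, species))
    }
  }

  draw <- function(idx) {
    vapply(idx, function(i) {
      a <- allowed[[i]]
      a[sample.int(length(a), 1L)]
    }, character(1))
  }
  residues <- draw(seq_len(L))
  redrawable <- vapply(allowed, function(a) length(a) > 1, logical(1))

  for (attempt in seq_len(max_attempts)) {
    seqstr <- paste(residues, collapse = "")
    bad_idx <- integer(0)
    for (ename in names(enzymes)) {
      enz <- enzymes[[ename]]
      actual <- .cut_positions(seqstr, enz)
      if (length(setdiff(expected[[ename]], actual))) {
        stop("internal error: planted ", ename, " site destroyed")
      }
      m <- nchar(enz$recognition)
      extra <- setdiff(find_sites(seqstr, enz),
                       planted[[ename]] %||% integer(0))
      for (s in extra) {
        win <- (s + 1):(s + m)
        fixable <- win[redrawable[win]]
        if (length(fixable) == 0) {
          stop(sprintf(
            "unintended %s site in %s at position %d lies entirely within fixed bases (primers or planted sites); constraints collide",
            ename, species, s))
        }
        bad_idx <- c(bad_idx, fixable)
      }
    }
    if (length(bad_idx) == 0) {
      return(dna_seq(seqstr,
                     id = gsub(" ", "_", species),
                     description = species))
    }
    residues[unique(bad_idx)] <- draw(unique(bad_idx))
  }
  stop("fixture construction for ", species, " did not converge in ",
       max_attempts, " attempts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a synthetic reference amplicon
#'
#' Constructs a 357-bp sequence that (a) begins with the forward primer
#' and ends with the reverse complement of the reverse primer, (b) digests
#' with each enzyme of the species' reference fingerprint into exactly the
#' reference fragment lengths, and (c) carries no unintended site for any
#' catalogue enzyme. Deterministic in \code{(species, seed)}: repeated
#' calls return byte-identical sequences.
#'
#' @param species Panel species (binomial, short code, or common name).
#' @param seed Integer seed for the random interior.
#' @param target_pattern Optional \code{\link{fragment_pattern}} to
#'   reproduce instead of the bundled reference row; its per-enzyme sums
#'   must all equal one length.
#' @param panel,enzymes,pair Reference panel, enzyme catalogue and primer
#'   pair (bundled defaults).
#' @param mutation_rate Per-base substitution probability applied to free
#'   interior bases (outside primers and planted sites) after
#'   construction, for generating noisy field-like samples. Default 0;
#'   nonzero rates may alter the fingerprint — that is their purpose.
#' @param max_attempts Retry budget for removing unintended sites.
#' @return A \code{\link{dna_seq}} of length 357 (for the bundled panel).
#' @export
build_amplicon <- function(species, seed = 1, target_pattern = NULL,
                           panel = reference_panel(),
                           enzymes = enzyme_catalogue(),
                           pair = cytb_primer_pair(),
                           mutation_rate = 0, max_attempts = 1000) {
  species <- .resolve_species(species, panel)
  target <- target_pattern %||% panel[[species]]
  L <- sum(panel[[species]][[1]])
  .with_seed(seed, {
    amp <- .build_amplicon_impl(species, target, enzymes, pair, L,
                                max_attempts)
    if (mutation_rate > 0) {
      amp <- .mutate_free(amp, target, enzymes, pair, mutation_rate)
    }
    amp$id <- sprintf("%s_seed%d", amp$id, seed)
    amp
  })
}

# noisy-sample knob: substitute free interior bases at the given rate
.mutate_free <- function(amp, target, enzymes, pair, rate) {
  res <- strsplit(amp$residues, "")[[1]]
  L <- length(res)
  fixed <- c(seq_len(nchar(pair$forward$sequence)),
             (L - nchar(reverse_complement(pair$reverse$sequence)) + 1):L)
  for (ename in intersect(names(enzymes), names(target))) {
    frags <- target[[ename]]
    if (length(frags) < 2) next
    enz <- enzymes[[ename]]
    for (s in find_sites(amp$residues, enz)) {
      fixed <- c(fixed, (s + 1):(s + nchar(enz$recognition)))
    }
  }
  free <- setdiff(seq_len(L), unique(fixed))
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) res[i] <- sample(setdiff(c("A", "C", "G", "T"), res[i]), 1)
  amp$residues <- paste(res, collapse = "")
  amp
}

#' Build a synthetic template with flanking sequence
#'
#' Embeds the species' reference amplicon between random flanks that
#' contain no primer match and create no second product, giving
#' \code{\link{amplify}} a realistic search problem. With
#' \code{strand = "-"} the whole construct is reverse-complemented, so
#' amplification must recover the same forward-orientation product.
#'
#' @inheritParams build_amplicon
#' @param flank_length Flank length in bp on each side (default 100).
#' @param strand \code{"+"} or \code{"-"}: strand on which the amplicon is
#'   embedded.
#' @return A \code{\link{dna_seq}} of length 357 + 2 * flank_length.
#' @export
build_template <- function(species, seed = 1, flank_length = 100,
                           strand = c("+", "-"), target_pattern = NULL,
                           panel = reference_panel(),
                           enzymes = enzyme_catalogue(),
                           pair = cytb_primer_pair(),
                           max_attempts = 1000) {
  strand <- match.arg(strand)
  stopifnot(flank_length >= 0)
  species <- .resolve_species(species, panel)
  target <- target_pattern %||% panel[[species]]
  L <- sum(panel[[species]][[1]])
  .with_seed(seed, {
    amp <- .build_amplicon_impl(species, target, enzymes, pair, L,
                                max_attempts)
    for (attempt in seq_len(100)) {
      left <- if (flank_length) .random_acgt(flank_length) else ""
      right <- if (flank_length) .random_acgt(flank_length) else ""
      res <- paste0(left, amp$residues, right)
      if (strand == "-") res <- reverse_complement(res)
      tmpl <- dna_seq(res,
                      id = sprintf("%s_seed%d_template", amp$id, seed),
                      description = species)
      prods <- amplify(tmpl, pair)
      if (length(prods) == 1 &&
          prods[[1]]$sequence$residues == amp$residues) {
        return(tmpl)
      }
    }
    stop("flank construction for ", species,
         " kept producing spurious primer sites")
  })
}

#' The bundled commercial-cohort composition
#'
#' The 39 market sashimi samples with their declared label and the species
#' established by sequencing: 10 labeled Atlantic bluefin (8 true
#' \emph{T. thynnus}, 2 \emph{T. alalunga}), 6 southern bluefin (all
#' true), 13 yellowfin (10 true, 3 \emph{T. obesus}), 10 bigeye (8 true,
#' 2 \emph{T. audax}).
#'
#' @param path Optional path to a cohort TSV (columns \code{id},
#'   \code{label}, \code{true_species}); defaults to the bundled table.
#' @return data.frame with columns \code{id}, \code{label},
#'   \code{true_species}.
#' @export
table_cohort <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "commercial_cohort.tsv",
                        package = "tunarflp", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a synthetic sample cohort
#'
#' One synthetic template per cohort row, built for the row's true species
#' with a per-sample seed derived from the cohort seed, plus the truth
#' table. Deterministic in \code{(cohort, seed)}.
#'
#' @param cohort data.frame with \code{id}, \code{label},
#'   \code{true_species} (default: the bundled 39-sample table).
#' @param seed Cohort seed (default 7).
#' @param flank_length Flank length per template.
#' @param panel,enzymes,pair Bundled defaults.
#' @return List with \code{samples} (list of \code{list(id, label,
#'   template)}) and \code{truth} (the input data.frame).
#' @export
build_cohort <- function(cohort = table_cohort(), seed = 7,
                         flank_length = 100, panel = reference_panel(),
                         enzymes = enzyme_catalogue(),
                         pair = cytb_primer_pair()) {
  stopifnot(nrow(cohort) > 0,
            all(c("id", "label", "true_species") %in% names(cohort)))
  sample_seeds <- .with_seed(seed,
                             sample.int(2147483647L, nrow(cohort)))
  samples <- lapply(seq_len(nrow(cohort)), function(i) {
    tmpl <- build_template(cohort$true_species[i], seed = sample_seeds[i],
                           flank_length = flank_length, panel = panel,
                           enzymes = enzymes, pair = pair)
    tmpl$id <- cohort$id[i]
    list(id = cohort$id[i], label = cohort$label[i], template = tmpl)
  })
  list(samples = samples, truth = cohort)
}

#' Write a cohort to FASTA plus truth TSV
#'
#' @param cohort Result of \code{\link{build_cohort}}.
#' @param fasta_path,truth_path Output paths.
#' @return Invisibly, \code{fasta_path}.
#' @export
write_cohort <- function(cohort, fasta_path, truth_path) {
  write_fasta(lapply(cohort$samples, `[[`, "template"), fasta_path)
  utils::write.table(cohort$truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(fasta_path)
}
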