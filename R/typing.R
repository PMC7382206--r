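# The identification core: reference signature panel, tolerance-aware
# fragment-pattern comparison, the staged species-calling key (four core
# enzymes, HindII as tiebreak for the bigeye/skipjack pair), and exhaustive
# diagnostic-panel minimization.

#' Construct a fragment pattern
#'
#' A fragment pattern is the assay's observable fingerprint: for each
#' enzyme, the multiset of fragment lengths (bp). Table order is kept for
#' display, but all downstream matching is order-free, because gel bands
#' carry no order information beyond size.
#'
#' @param fragments Named list: enzyme name to integer vector of fragment
#'   lengths (all >= 1). Enzymes not assayed are simply absent.
#' @param provenance \code{"predicted"} (from sequence) or
#'   \code{"observed"} (read off a gel).
#' @return An object of class \code{fragment_pattern}.
#' @export
fragment_pattern <- function(fragments,
                             provenance = c("predicted", "observed")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(fragments), !is.null(names(fragments)),
            all(nzchar(names(fragments))))
  fragments <- lapply(fragments, function(f) {
    f <- as.integer(f)
    if (length(f) == 0 || any(f < 1)) stop("fragment lengths must be >= 1")
    f
  })
  structure(fragments, provenance = provenance, class = "fragment_pattern")
}

#' @export
print.fragment_pattern <- function(x, ...) {
  cat(sprintf("<fragment_pattern> (%s)\n", attr(x, "provenance")))
  for (e in names(x)) cat(sprintf("  %-8s %s\n", e,
                                  paste(x[[e]], collapse = ", ")))
  invisible(x)
}

#' Load the bundled eight-species reference panel
#'
#' Reads the reference signature table shipped with the package (one row
#' per species x enzyme; \code{-} marks an enzyme not assayed for that
#' species — HindII was only run for bigeye and skipjack tuna, whose four
#' core-enzyme fingerprints are identical). Asserts that the eight joint
#' patterns are pairwise distinct.
#'
#' @param path Optional path to a panel TSV with columns \code{code},
#'   \code{species}, \code{common_name}, \code{enzyme}, \code{fragments}
#'   (comma-joined bp, or \code{-}); defaults to the bundled table.
#' @return Named list (species to \code{\link{fragment_pattern}}) of class
#'   \code{reference_panel}, with a \code{meta} attribute giving each
#'   species' short code and common name.
#' @export
reference_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cytb_reference_panel.tsv",
                        package = "tunarflp", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "enzyme", "fragments")
  if (!all(need %in% names(tab))) {
    stop("panel table must have columns: ", paste(need, collapse = ", "))
  }
  species <- unique(tab$species)
  panel <- lapply(species, function(sp) {
    rows <- tab[tab$species == sp & tab$fragments != "-", , drop = FALSE]
    frags <- lapply(strsplit(rows$fragments, ","), as.integer)
    names(frags) <- rows$enzyme
    fragment_pattern(frags, provenance = "predicted")
  })
  names(panel) <- species
  # the eight joint signatures must be pairwise distinct (exact comparison)
  exact <- match_config(abs_tolerance = 0, rel_tolerance = 0,
                        min_detectable = 0)
  for (i in seq_along(panel)) {
    for (j in seq_len(i - 1L)) {
      if (!.patterns_differ(panel[[i]], panel[[j]], exact)) {
        stop("panel species '", species[i], "' and '", species[j],
             "' have identical joint patterns")
      }
    }
  }
  meta <- unique(tab[, intersect(c("code", "species", "common_name"),
                                 names(tab)), drop = FALSE])
  structure(panel, meta = meta, class = "reference_panel")
}

#' Matching configuration
#'
#' Tolerances for comparing observed gel patterns against predicted
#' reference patterns, and the staged-key layout.
#'
#' @param abs_tolerance Absolute band-size tolerance in bp (default 5).
#' @param rel_tolerance Relative tolerance as a fraction of the larger
#'   band (default 0.10); the effective tolerance for a pair of bands is
#'   the larger of the two.
#' @param min_detectable Bands below this size (bp) are dropped from both
#'   sides before matching (default 20): a 10-bp fragment is unresolvable
#'   on a 3\% agarose gel, so the bigeye-tuna HindII reference
#'   (150, 10, 197) must be matchable from its two visible bands.
#' @param core_enzymes Enzymes used in stage 1 of the key.
#' @param tiebreak_enzyme Enzyme consulted only when stage 1 narrows the
#'   call to exactly the bigeye/skipjack pair (default HindII).
#' @param single_stage If \code{TRUE}, skip the staged key and compare on
#'   all assayed enzymes at once.
#' @return An object of class \code{match_config}.
#' @export
match_config <- function(abs_tolerance = 5, rel_tolerance = 0.10,
                         min_detectable = 20,
                         core_enzymes = c("Eco147I", "HinfI", "MboI", "XagI"),
                         tiebreak_enzyme = "HindII",
                         single_stage = FALSE) {
  stopifnot(abs_tolerance >= 0, rel_tolerance >= 0, min_detectable >= 0)
  structure(
    list(abs_tolerance = abs_tolerance, rel_tolerance = rel_tolerance,
         min_detectable = min_detectable, core_enzymes = core_enzymes,
         tiebreak_enzyme = tiebreak_enzyme, single_stage = single_stage),
    class = "match_config"
  )
}

#' Exact-match configuration
#'
#' Zero tolerance, no detection limit: appropriate when both patterns are
#' predicted from sequence (e.g. panel design), where band sizes are exact.
#' @return A \code{\link{match_config}}.
#' @export
exact_config <- function() {
  match_config(abs_tolerance = 0, rel_tolerance = 0, min_detectable = 0)
}

# one enzyme's band lists match under the config?
.bands_match <- function(a, b, config) {
  a <- sort(a[a >= config$min_detectable])
  b <- sort(b[b >= config$min_detectable])
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0) return(TRUE)
  tol <- pmax(config$abs_tolerance, config$rel_tolerance * pmax(a, b))
  all(abs(a - b) <= tol)
}

#' Compare two fragment patterns
#'
#' Per enzyme, drops bands below the detection limit on both sides, then
#' pairs the remaining bands smallest-to-largest as multisets; two bands
#' match when their difference is within the larger of the absolute and
#' relative tolerance. An enzyme matches when a perfect one-to-one pairing
#' exists. Enzymes absent from either pattern are excluded (not failures);
#' the overall verdict requires every shared enzyme to match.
#'
#' @param observed,reference \code{\link{fragment_pattern}} objects (or
#'   plain named lists of fragment vectors).
#' @param config A \code{\link{match_config}}.
#' @return List with \code{per_enzyme} (named logical over shared enzymes)
#'   and \code{overall} (logical).
#' @export
compare_patterns <- function(observed, reference, config = match_config()) {
  shared <- intersect(names(observed), names(reference))
  if (length(shared) == 0) stop("patterns share no enzymes")
  per <- vapply(shared, function(e) {
    .bands_match(observed[[e]], reference[[e]], config)
  }, logical(1))
  list(per_enzyme = per, overall = all(per))
}

# restricted comparison used by identify(): do the two patterns match on
# the given enzymes (only those present in both)? NA if none shared.
.match_on <- function(observed, reference, enzymes, config) {
  shared <- intersect(enzymes, intersect(names(observed), names(reference)))
  if (length(shared) == 0) return(NA)
  all(vapply(shared, function(e) {
    .bands_match(observed[[e]], reference[[e]], config)
  }, logical(1)))
}

.patterns_differ <- function(a, b, config) {
  m <- .match_on(a, b, union(names(a), names(b)), config)
  isFALSE(m)
}

#' Identify the species of a query
#'
#' The assay's calling key. Stage 1 compares the query against every panel
#' species on the four core enzymes; a unique match is called directly.
#' When stage 1 returns exactly the bigeye tuna / skipjack tuna pair —
#' the only two species with identical core fingerprints — stage 2
#' consults the tiebreak enzyme (HindII) and calls the unique survivor;
#' if the query carries no HindII data the ambiguity is reported with a
#' warning, never guessed. Any other multi-species or empty match set is
#' returned as an ambiguity set or no-match.
#'
#' @param query A \code{\link{fragment_pattern}}, or a sequence
#'   (\code{dna_seq} / \code{amplicon} / string) that is first digested
#'   with the bundled catalogue.
#' @param panel A \code{\link{reference_panel}}.
#' @param config A \code{\link{match_config}}; set
#'   \code{single_stage = TRUE} to compare on all assayed enzymes at once.
#' @param id Query identifier used in the result.
#' @return An \code{identification_result}: list with \code{id},
#'   \code{call} (species name, or \code{NA} when not unique),
#'   \code{ambiguity} (character vector of candidate species),
#'   \code{per_enzyme} (agreement flags against the called species, when
#'   called) and \code{warnings}.
#' @export
identify_species <- function(query, panel = reference_panel(),
                             config = match_config(), id = NULL) {
  warns <- character(0)
  if (!inherits(query, "fragment_pattern") && !is.list(query)) {
    query <- digest_panel(query)
  } else if (inherits(query, c("dna_seq", "amplicon"))) {
    query <- digest_panel(query)
  }
  if (length(query) == 0) stop("query pattern has no enzymes")
  if (is.null(id)) id <- "query"

  stage1_enzymes <- if (config$single_stage) {
    unique(unlist(lapply(panel, names)))
  } else config$core_enzymes
  m1 <- vapply(panel, function(ref) {
    isTRUE(.match_on(query, ref, stage1_enzymes, config))
  }, logical(1))
  cand <- names(panel)[m1]

  if (!config$single_stage && length(cand) == 2) {
    # stage 2: tiebreak enzyme, applicable only when both candidates carry it
    tb <- config$tiebreak_enzyme
    have_tb <- vapply(panel[cand], function(ref) tb %in% names(ref),
                      logical(1))
    if (all(have_tb)) {
      if (tb %in% names(query)) {
        m2 <- vapply(panel[cand], function(ref) {
          isTRUE(.match_on(query, ref, tb, config))
        }, logical(1))
        cand <- cand[m2]
      } else {
        warns <- c(warns, sprintf(
          "tiebreak enzyme %s required to resolve {%s} but absent from query",
          tb, paste(cand, collapse = ", ")))
      }
    }
  }

  call <- if (length(cand) == 1) cand else NA_character_
  per <- if (!is.na(call)) {
    compare_patterns(query, panel[[call]], config)$per_enzyme
  } else NULL
  if (length(cand) == 0) warns <- c(warns, "no panel species matches")
  structure(
    list(id = id, call = call, ambiguity = cand, per_enzyme = per,
         warnings = warns),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  verdict <- if (!is.na(x$call)) x$call
  else if (length(x$ambiguity)) paste0("ambiguous {",
                                       paste(x$ambiguity, collapse = ", "), "}")
  else "no match"
  cat(sprintf("<identification> %s: %s\n", x$id, verdict))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Smallest fully discriminating enzyme subset
#'
#' Exhaustive search over all non-empty subsets of the panel's enzymes
#' (31 subsets for the bundled five-enzyme catalogue), ordered by size
#' and then lexicographic name order, for the first subset under which
#' every pair of panel species is distinguishable: two species are
#' distinguishable when at least one subset enzyme is assayed in both and
#' their band lists fail to match under the config. Enzymes not assayed
#' for a species (HindII for six of the eight) cannot distinguish it.
#' Above 20 enzymes a greedy set-cover fallback replaces the exhaustive
#' scan.
#'
#' @param panel A \code{\link{reference_panel}}.
#' @param config A \code{\link{match_config}}; defaults to
#'   \code{\link{exact_config}} because panel design compares predicted
#'   patterns, where band sizes are exact.
#' @return List with \code{enzymes} (the minimal subset), \code{size},
#'   \code{discriminating} (FALSE when even the full catalogue fails, in
#'   which case the full set is returned flagged), \code{partition} (the
#'   species groups left indistinguishable under the subset) and
#'   \code{by_size} (data.frame: for each subset size below the minimum,
#'   the best-achievable number of distinguishable classes and a subset
#'   attaining it).
#' @export
minimal_panel <- function(panel, config = exact_config()) {
  species <- names(panel)
  if (length(species) < 2) {
    return(list(enzymes = character(0), size = 0L, discriminating = TRUE,
                partition = as.list(species),
                by_size = data.frame(size = integer(0), best_classes =
                                       integer(0), subset = character(0))))
  }
  enzymes <- sort(unique(unlist(lapply(panel, names))))
  pairs <- utils::combn(length(species), 2)
  # separates[e, p]: does enzyme e distinguish species pair p?
  separates <- matrix(FALSE, length(enzymes), ncol(pairs),
                      dimnames = list(enzymes, NULL))
  for (e in enzymes) {
    for (p in seq_len(ncol(pairs))) {
      a <- panel[[pairs[1, p]]]; b <- panel[[pairs[2, p]]]
      if (e %in% names(a) && e %in% names(b)) {
        separates[e, p] <- !.bands_match(a[[e]], b[[e]], config)
      }
    }
  }
  partition_of <- function(subset) {
    sep <- if (length(subset)) {
      apply(separates[subset, , drop = FALSE], 2, any)
    } else rep(FALSE, ncol(pairs))
    grp <- seq_along(species)
    for (p in which(!sep)) {
      g <- grp[pairs[, p]]
      grp[grp == max(g)] <- min(g)
    }
    unname(split(species, grp))
  }
  n_classes <- function(subset) length(partition_of(subset))

  if (length(enzymes) > 20) {
    # greedy set cover on undistinguished pairs
    chosen <- character(0)
    left <- seq_len(ncol(pairs))
    while (length(left)) {
      gain <- vapply(setdiff(enzymes, chosen), function(e) {
        sum(separates[e, left])
      }, numeric(1))
      if (all(gain == 0)) break
      pick <- names(which.max(gain))
      chosen <- c(chosen, pick)
      left <- left[!separates[pick, left]]
    }
    ok <- length(left) == 0
    return(list(enzymes = sort(chosen), size = length(chosen),
                discriminating = ok, partition = partition_of(chosen),
                by_size = data.frame()))
  }

  by_size <- data.frame(size = integer(0), best_classes = integer(0),
                        subset = character(0), stringsAsFactors = FALSE)
  for (k in seq_along(enzymes)) {
    subs <- utils::combn(enzymes, k, simplify = FALSE)  # lexicographic order
    classes <- vapply(subs, n_classes, integer(1))
    hit <- which(classes == length(species))
    if (length(hit)) {
      subset <- subs[[hit[1]]]
      return(list(enzymes = subset, size = k, discriminating = TRUE,
                  partition = partition_of(subset), by_size = by_size))
    }
    best <- which.max(classes)
    by_size <- rbind(by_size, data.frame(
      size = k, best_classes = classes[best],
      subset = paste(subs[[best]], collapse = "+"),
      stringsAsFactors = FALSE))
  }
  list(enzymes = enzymes, size = length(enzymes), discriminating = FALSE,
       partition = partition_of(enzymes), by_size = by_size)
}

#' Classify a cohort of samples
#'
#' Runs the full assay per sample — in-silico PCR when a template is
#' supplied, panel digestion, staged identification — and tabulates calls
#' against the declared labels, flagging samples whose molecular call
#' contradicts the label (suspected mislabeling). Samples yielding no
#' amplicon are recorded as \code{"no amplification"} and excluded from
#' the concordance denominator with a warning; multi-product templates
#' are identified from their first product and flagged.
#'
#' @param cohort Either the list returned by \code{\link{build_cohort}}, or
#'   a list of samples, each a list with \code{id}, \code{label}
#'   (optional) and one of \code{template} (\code{dna_seq}),
#'   \code{amplicon}, or \code{pattern} (\code{fragment_pattern}).
#' @param panel,config See \code{\link{identify_species}}.
#' @param pair Primer pair used when templates must be amplified.
#' @return List with \code{results} (one data.frame row per sample: id,
#'   label, call, ambiguity, n_amplicons, mislabeled, warnings) and
#'   \code{concordance} (contingency table of label vs call over amplified
#'   samples).
#' @export
classify_cohort <- function(cohort, panel = reference_panel(),
                            config = match_config(),
                            pair = cytb_primer_pair()) {
  if (!is.null(cohort$samples)) cohort <- cohort$samples
  if (length(cohort) == 0) {
    return(list(results = data.frame(id = character(0), label = character(0),
                                     call = character(0),
                                     ambiguity = character(0),
                                     n_amplicons = integer(0),
                                     mislabeled = logical(0),
                                     warnings = character(0)),
                concordance = table(character(0), character(0))))
  }
  rows <- lapply(cohort, function(s) {
    label <- if (is.null(s$label)) NA_character_ else s$label
    n_amp <- NA_integer_
    warns <- character(0)
    if (!is.null(s$pattern)) {
      qry <- s$pattern
    } else if (!is.null(s$amplicon)) {
      qry <- s$amplicon
    } else {
      amps <- amplify(s$template, pair)
      n_amp <- length(amps)
      if (n_amp == 0) {
        return(data.frame(id = s$id, label = label,
                          call = "no amplification", ambiguity = "",
                          n_amplicons = 0L, mislabeled = NA,
                          warnings = "no amplicon in product-length window",
                          stringsAsFactors = FALSE))
      }
      if (n_amp > 1) warns <- c(warns, sprintf("%d amplicons; using first",
                                               n_amp))
      qry <- amps[[1]]
    }
    res <- identify_species(qry, panel, config, id = s$id)
    call <- if (!is.na(res$call)) res$call
    else if (length(res$ambiguity)) paste0(
      "ambiguous {", paste(res$ambiguity, collapse = ","), "}")
    else "no match"
    warns <- c(warns, res$warnings)
    mis <- if (is.na(label) || is.na(res$call)) NA else {
      !.labels_agree(label, res$call, panel)
    }
    data.frame(id = s$id, label = label, call = call, ambiguity =
                 paste(res$ambiguity, collapse = ","),
               n_amplicons = n_amp, mislabeled = mis,
               warnings = paste(warns, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- results$call != "no amplification"
  concordance <- table(label = results$label[ok], call = results$call[ok])
  list(results = results, concordance = concordance)
}

# a declared market label agrees with a species call when it equals the
# species name, its short code, or its common name in the panel metadata
.labels_agree <- function(label, species, panel) {
  if (identical(label, species)) return(TRUE)
  meta <- attr(panel, "meta")
  if (is.null(meta)) return(FALSE)
  row <- meta[meta$species == species, , drop = FALSE]
  if (nrow(row) == 0) return(FALSE)
  tolower(label) %in% tolower(unlist(row))
}
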