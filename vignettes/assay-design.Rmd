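---
title: "Design of the in-silico PCR-RFLP tuna authentication assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the in-silico PCR-RFLP tuna authentication assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunarflp)
```

# The assay model

PCR-RFLP species identification rests on two observations: a universal
primer pair amplifies the same 357-bp stretch of the mitochondrial *Cytb*
gene across the eight target species, and fixed interspecific substitutions
create or destroy restriction sites inside it. The observable is therefore
not the sequence but a *fragment-length fingerprint*: for each enzyme, the
multiset of band sizes on a gel. This package simulates every step of that
chain.

**Virtual PCR.** `amplify()` pairs every forward-primer hit with every
correctly oriented reverse-primer hit and reports all products in a length
window. Defaults: zero mismatches, a 3-base 3' clamp (mismatches at the
polymerase extension end are disqualifying), and a product window of
300–400 bp bracketing the expected 357. The match stringency of the
original wet-lab primers is not documented anywhere we could rely on, so
exact matching was chosen as the conservative default and is exposed as a
parameter (`max_mismatches`, `clamp_3prime`). Degenerate template bases are
compared permissively (intersect-mode IUPAC matching): an `N` in a field
sequence should not abolish a primer hit. Coordinates are 0-based
half-open throughout, so fragment arithmetic is exact and
`end − start` is always the product length.

**Digestion.** `digest()` performs complete single-enzyme digestion of a
linear sequence: site scan, add the enzyme's top-strand cut offset,
deduplicate, drop cuts at the termini (a terminal nick yields no new band),
and difference to fragments. Two semantic choices matter:

* *Subset-mode matching for sites.* A sequence base creates a site only if
  its IUPAC set is contained in the recognition letter's set — an ambiguous
  base cannot be guaranteed cleavable. Intersect mode is available to scan
  for *potential* hidden sites.
* *Single top-strand scan.* All five bundled recognition patterns equal
  their own IUPAC reverse complement; this is asserted when the catalogue
  loads, not assumed. A user-supplied non-palindromic enzyme is handled by
  additionally scanning the reverse-complemented pattern with the mirrored
  offset.

The recognition sequences and offsets are the standard public definitions
(Eco147I is an isoschizomer of StuI, XagI of EcoNI, HindII of HincII);
the fragment arithmetic against the bundled reference fingerprints
validates them: every per-enzyme fragment list sums to 357.

Note that only the blunt cutters (Eco147I, HindII) cut at the center of
their site; HinfI (offset 1/5), MboI (0/4) and XagI (5/11) do not, so
reverse-complementing a sequence reverses their *site* positions but not
the top-strand cut coordinates. The test suite asserts exactly this.

**Matching and the staged key.** Gel bands carry no order information, so
`compare_patterns()` compares per-enzyme band lists as multisets, pairing
sorted lists elementwise with tolerance
`max(abs_tolerance, rel_tolerance · larger band)`. Defaults — 5 bp
absolute, 10% relative, 20 bp detection limit — are design choices for
3% agarose gels, not measured values: band-size read-off error grows with
size (hence the relative term) and a 10-bp fragment runs off the gel
(hence the limit, which drops sub-limit bands from *both* sides so the
bigeye-tuna HindII reference 150/10/197 is matchable from its two visible
bands). Enzymes absent from either pattern are excluded rather than
failed, because the reference panel itself assays HindII for only two
species.

`identify_species()` implements the assay's economy literally: stage 1
compares on the four core enzymes; only when the match set is exactly the
bigeye/skipjack pair is HindII consulted. Ambiguity is reported, never
resolved by preference — a diagnostic tool must not guess. A
`single_stage` switch compares on all assayed enzymes at once for users
who run all five digests anyway.

`minimal_panel()` answers "are all five enzymes needed?" by exhaustive
search over the 31 non-empty subsets, ordered by size then name, with a
greedy set-cover fallback above 20 enzymes (exactness is cheap at panel
scale). It defaults to exact, zero-tolerance comparison because panel
design compares *predicted* patterns, where sizes are exact; under either
the exact or the gel configuration the bundled answer is the same: size 5,
with each enzyme uniquely required by at least one species pair (HindII
for bigeye/skipjack, MboI for Atlantic/southern bluefin, XagI for
yellowfin vs that pair, Eco147I for marlin/swordfish, HinfI for southern
bluefin/skipjack).

# The synthetic-sequence generator

`build_amplicon()` is constructive, not simulative. It maintains a
per-position set of allowed bases over the 357 positions: primer positions
are fixed to the primer residues, positions inside planted recognition
sites are restricted to the site letter's IUPAC set (intersected where
sites overlap), everything else is free ACGT. Cut positions are the
cumulative sums of the reference fragment list, so every draw from the
allowed sets contains all required sites by construction; a verify loop
then eliminates *unintended* sites for any catalogue enzyme by redrawing
the free bases they cover (bounded retries, seeded, deterministic in
`(species, seed)`).

Two placement subtleties were genuinely open:

* *Fragment order.* The reference tables list fragments in one order, and
  the generator plants cuts in that order by preference. For striped
  marlin, however, the listed orders are jointly unsatisfiable — an
  Eco147I site at cut 198 and a HinfI site at cut 196 would demand
  contradictory bases at position 195 — so the generator falls back to
  another permutation of one enzyme's fragment list (here HinfI as
  161/196). Since all downstream matching is order-free, any order
  reproduces the reference multiset; the fallback is deterministic
  (listed order first, then permutations in a fixed order).
* *Overlapping sites.* The bigeye-tuna HindII site at cut 160 overlaps the
  HinfI site at cut 161; the overlap is IUPAC-compatible (`R∩G`, `A∩A`,
  `C∩N`) and the allowed-set intersection resolves it without any special
  casing.

`build_template()` wraps the amplicon in random flanks verified to create
no spurious primer hit or second product, optionally on the minus strand;
`build_cohort()` builds one template per row of the bundled 39-sample
market-cohort table (per-sample seeds derived from the cohort seed), whose
label/true-species composition encodes the documented mislabeling pattern:
2 of 10 "Atlantic bluefin" samples are albacore, 3 of 13 "yellowfin" are
bigeye, 2 of 10 "bigeye" are striped marlin, and all 6 "southern bluefin"
are genuine.

**What the generator does and does not emulate.** Fixtures are
signature-faithful: they carry exactly the diagnostic fingerprint, the
primer ends, and nothing else. They do not model real *Cytb* evolution —
no codon structure, no transition bias, no cross-species homology outside
the planted sites (the shared HinfI cut at 109 across *Thunnus* arises
per-row, not from a shared ancestor). Consequently, green tests show the
*assay logic* is correct (fingerprints are computed, matched and called
exactly as specified), not that real sequences produce these fingerprints;
validating against GenBank *Cytb* records would require network access and
is deliberately out of scope. The `mutation_rate` knob substitutes free
interior bases to create noisy field-like samples for tolerance testing;
it can, by design, alter fingerprints.

# The verification phylogeny

The assay's wet-lab validation cross-checks RFLP calls against a *Cytb*
tree; the `phylo` module reproduces that machinery. `k2p_distance()` is
implemented in-package because callers need the transition/transversion
split and an explicit saturation flag: with transition proportion P and
transversion proportion Q over included sites,
d = −½·ln((1−2P−Q)·√(1−2Q)), undefined (flagged, not thrown) when either
log argument is non-positive. Ambiguous sites are deleted *pairwise*
rather than across the whole alignment — it wastes less signal, and the
choice only matters for gappy data. Tree building is delegated to ape's
neighbor-joining, with two post-conditions enforced here: negative branch
lengths are clamped to zero with the negative amount transferred to the
sibling branch (preserving total tree length), and bootstrap supports are
computed from per-replicate RNG streams derived from the master seed by
counter, so results are reproducible regardless of evaluation order.
Replicates where some pair saturates are skipped and counted, with a
warning above 5%. NJ joining ties are resolved by ape's deterministic
lowest-index rule, which the equidistant-taxa case exercises.

# Numerical and testing choices

Degenerate inputs are handled explicitly: empty FASTA yields an empty
result, a template without primer sites yields zero amplicons ("no
amplification" in cohort reports, excluded from concordance denominators),
a homopolymer digests to one full-length fragment, and coincident cuts
deduplicate. Gap characters are rejected rather than stripped — silent
stripping would shift every cut coordinate.

The test suite uses problem sizes chosen to exercise the combinatorics
while keeping a full run under a minute: 1,000 random digests for
fragment-sum conservation, 1,000 random 500-mers for the site-scan oracle
comparison (against a naive per-position scanner), 8 species × 3 seeds
for fixture round-trips plus the full 39-sample cohort, and 50–100
bootstrap replicates on an 8-taxon alignment with planted diagnostic
columns (the assay's published protocol uses 1,000 replicates; supports
converge long before that on such data).

# Known limitations

* The reference fingerprints cover exactly eight species; a sample from
  any other species will either fail to amplify, return "no match", or —
  worst case — collide with a reference fingerprint. The tool reports, it
  does not prove.
* Mixtures (two species in one sample) are out of scope; fragment
  patterns of mixtures superimpose and would need deconvolution.
* Complete digestion is assumed; partial digests, star activity and
  methylation sensitivity are not modeled.
* Band tolerances are gel-reading heuristics, exposed as configuration;
  they are not fitted to densitometry data.
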