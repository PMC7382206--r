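# Independent oracles and small generators used across the suite.

# random residue string over a given alphabet
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

iupac_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

# per-base complement lookup, independent of the implementation's chartr
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# naive O(n*m) per-position sliding-window site scan
oracle_find_sites <- function(seq, pattern, mode = "subset") {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  n <- length(sc)
  m <- length(pc)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (p in 0:(n - m)) {
    if (all(iupac_match(pc, sc[(p + 1):(p + m)], mode))) {
      hits <- c(hits, p)
    }
  }
  hits
}

# the bundled reference signatures, written out independently of the
# packaged TSV, for asserting what reference_panel() loads
expected_signatures <- list(
  "Thunnus alalunga" = list(Eco147I = c(233L, 124L),
                            HinfI = c(109L, 52L, 196L),
                            MboI = 357L, XagI = 357L),
  "Thunnus albacares" = list(Eco147I = 357L, HinfI = c(109L, 52L, 196L),
                             MboI = 357L, XagI = c(101L, 256L)),
  "Thunnus thynnus" = list(Eco147I = 357L, HinfI = c(109L, 248L),
                           MboI = c(62L, 295L), XagI = 357L),
  "Thunnus maccoyii" = list(Eco147I = 357L, HinfI = c(109L, 248L),
                            MboI = 357L, XagI = 357L),
  "Tetrapturus audax" = list(Eco147I = c(124L, 74L, 159L),
                             HinfI = c(196L, 161L), MboI = 357L,
                             XagI = 357L),
  "Xiphias gladius" = list(Eco147I = c(283L, 74L), HinfI = c(196L, 161L),
                           MboI = 357L, XagI = 357L),
  "Thunnus obesus" = list(Eco147I = 357L, HinfI = c(109L, 52L, 196L),
                          MboI = 357L, XagI = 357L,
                          HindII = c(150L, 10L, 197L)),
  "Katsuwonus pelamis" = list(Eco147I = 357L, HinfI = c(109L, 52L, 196L),
                              MboI = 357L, XagI = 357L, HindII = 357L)
)

# hierarchical test alignment: two 4-taxon clades with diagnostic column
# blocks for the between-clade split and for one subclade inside each
make_clade_alignment <- function(seed, L = 150) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  taxa <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4")
  mk <- function(id, i) {
    s <- base
    if (grepl("^b", id)) s[1:30] <- "T" else s[1:30] <- "A"
    if (id %in% c("a1", "a2")) s[31:50] <- "G"
    if (id %in% c("b1", "b2")) s[51:70] <- "C"
    s[90 + i] <- setdiff(c("A", "C", "G", "T"), s[90 + i])[1]
    dna_seq(paste(s, collapse = ""), id = id)
  }
  lapply(seq_along(taxa), function(i) mk(taxa[i], i))
}
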