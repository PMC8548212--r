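# independent oracles, kept deliberately naive

# hand-written standard genetic code (codon -> single-letter aa, stop = "*")
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# translate from `start` until the first stop (or sequence end), N codons -> X
oracle_translate <- function(seq, start) {
  aa <- character(0)
  p <- start
  while (p + 2 <= nchar(seq)) {
    cod <- substr(seq, p, p + 2)
    if (grepl("N", cod)) {
      aa <- c(aa, "X")
    } else {
      r <- CODON_TABLE[[cod]]
      if (r == "*") return(list(protein = paste(aa, collapse = ""),
                                stop_end = p + 2, open = FALSE))
      aa <- c(aa, r)
    }
    p <- p + 3
  }
  list(protein = paste(aa, collapse = ""), stop_end = NA, open = TRUE)
}

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# quadratic longest-common-suffix
oracle_common_suffix <- function(a, b) {
  best <- 0
  for (k in seq_len(min(nchar(a), nchar(b)))) {
    if (substring(a, nchar(a) - k + 1) == substring(b, nchar(b) - k + 1))
      best <- k
  }
  best
}

# Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Pearson chi-square on a 2x2, no continuity correction
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# exhaustive subset-filter template enumeration (chains mode)
oracle_chains <- function(ids, start_exons, terminal_exon,
                          required = character(0), excluded = character(0),
                          max_len = Inf) {
  n <- length(ids)
  out <- list()
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    chain <- ids[sel]
    if (!(chain[1] %in% start_exons)) next
    if (chain[length(chain)] != terminal_exon) next
    if (!all(required %in% chain)) next
    if (any(excluded %in% chain)) next
    if (length(chain) > max_len) next
    out[[length(out) + 1]] <- chain
  }
  sort(vapply(out, paste, character(1), collapse = "-"))
}

# per-offset PWM score by explicit loop
oracle_scan <- function(window, logodds) {
  chars <- strsplit(window, "")[[1]]
  w <- ncol(logodds)
  n <- length(chars) - w + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(off) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[off + j - 1]
      s <- s + if (b %in% rownames(logodds)) logodds[b, j] else 0
    }
    s
  }, numeric(1))
}
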