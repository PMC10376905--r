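# Independent brute-force oracles and fixture builders used across the suite.

# MCC straight from its printed formula, no shortcuts shared with the
# implementation path
oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fn) * sqrt(tn + fp)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# kappa from explicit observed/expected agreement
oracle_kappa <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  p_yes <- ((tp + fp) / n) * ((tp + fn) / n)
  p_no <- ((fn + tn) / n) * ((fp + tn) / n)
  pe <- p_yes + p_no
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

# AUC as the normalized Mann-Whitney U: loop over all (positive, negative)
# pairs, ties count half
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# labeled feature table with the full 14-column layout where the class is
# perfectly separable on the MAF sentinel; all remaining columns are noise
# or constants
make_separable_table <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  data.frame(
    chr = sample(1:22, n, replace = TRUE),
    POS = sample.int(1e6, n),
    TypeBin = sample(0:2, n, replace = TRUE),
    Exon = sample(0:15, n, replace = TRUE),
    Freq = round(runif(n, 0.05, 1), 2),
    MAFbin = ifelse(y == 1, -1, round(runif(n, 0.05, 0.5), 4)),
    Coverage = sample(300:2000, n, replace = TRUE),
    Protbin = sample(0:2, n, replace = TRUE),
    aarefbin = sample(1:21, n, replace = TRUE),
    aamutbin = sample(1:22, n, replace = TRUE),
    aarefChemical = sample(c(1.1, 2.3, 3.1, 4.2), n, replace = TRUE),
    aamutChemicalVal = sample(c(1.4, 2.5, 3.2, 4.3), n, replace = TRUE),
    Grantham = sample(c(-1, 5, 58, 101, 215), n, replace = TRUE),
    varEffectBin = sample(c(-1, 0, 1, 2, 3), n, replace = TRUE),
    isMut = y
  )
}

# three hand-written annotation rows as a TSV file; returns the path
write_tiny_tsv <- function(path = tempfile(fileext = ".tsv"),
                           drop_column = NULL, maf_blank_row = 1L) {
  header <- c("chrom", "pos", "gene", "variant_type", "exon", "coding",
              "protein", "vaf", "maf", "coverage", "effect", "label")
  rows <- list(
    c("2", "25468888", "DNMT3A", "SNV", "11", "c.1266G>A", "p.Leu422=",
      "0.49", "0.224", "1810", "synonymous", "0"),
    c("19", "13054564", "CALR", "SNV", "9", "c.1154A>C", "p.Lys385Thr",
      "0.45", "", "900", "missense", "1"),
    c("4", "106196213", "TET2", "SNV", "11", "c.4553C>A", "p.Ser1518Ter",
      "0.38", "", "1500", "nonsense", "1")
  )
  if (!is.null(maf_blank_row)) {
    rows[[maf_blank_row]][9] <- rows[[maf_blank_row]][9]
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- header
  if (!is.null(drop_column)) {
    tab <- tab[, setdiff(colnames(tab), drop_column), drop = FALSE]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small sphere-style spaces shared by optimizer tests
sphere_objective <- function(p) -sum(p^2)
box3 <- function() search_space(c("x", "y", "z"), rep(-5, 3), rep(5, 3))
box1 <- function() search_space("x", 0, 4)
quad1 <- function(p) -(p[1] - 2)^2
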