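# Amino-acid lookup tables used by the variant codec: the ordinal index the
# model sees, the side-chain polarity codes, and the Grantham distance matrix.

AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

AA_ONE_TO_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", U = "Sec"
)

# Ordinal codes of the reference-side residue column. Selenocysteine (Sec)
# carries its own code even though it never occurs in the myeloid panel.
AA_INDEX_REF <- c(
  Arg = 1, His = 2, Lys = 3, Asp = 4, Glu = 5, Ser = 6, Thr = 7, Asn = 8,
  Gln = 9, Trp = 10, Sec = 11, Gly = 12, Pro = 13, Ala = 14, Val = 15,
  Ile = 16, Leu = 17, Met = 18, Phe = 19, Tyr = 20, Cys = 21
)

# The mutant-side column extends the residue codes with a shared code 22 for
# consequences that do not put a single residue at the site: frameshifts,
# premature stops, and deletions (duplications are grouped with these; the
# grouping of `dup` is a documented convention, see the methods vignette).
AA_INDEX_MUT <- c(AA_INDEX_REF, fs = 22, Ter = 22, del = 22, dup = 22)

# Side-chain polarity groups, encoded as group.member decimals:
# apolar 1.x, polar uncharged 2.x, negatively charged 3.x, positively
# charged 4.x; non-residue tokens carry 0.0.
AA_CHEMICAL <- c(
  Ala = 1.1, Phe = 1.2, Ile = 1.3, Leu = 1.4, Met = 1.5, Pro = 1.6,
  Val = 1.7, Trp = 1.8, Gly = 1.9,
  Cys = 2.1, Asn = 2.3, Gln = 2.4, Ser = 2.5, Thr = 2.6, Tyr = 2.7,
  Asp = 3.1, Glu = 3.2,
  His = 4.1, Lys = 4.2, Arg = 4.3,
  Ter = 0.0, dup = 0.0, del = 0.0, `p.?` = 0.0, `p.(=)` = 0.0, fs = 0.0,
  Sec = 0.0, `NA` = 0.0
)

# Grantham (1974) physico-chemical distances between the 20 standard amino
# acids (composition, polarity, molecular volume). Off-diagonal values span
# [5, 215]: Leu/Ile = 5 is the most conservative pair, Cys/Trp = 215 the most
# radical. Stored as the upper triangle in the conventional row order.
.grantham_order <- c("Ser", "Arg", "Leu", "Pro", "Thr", "Ala", "Val", "Gly",
                     "Ile", "Phe", "Tyr", "Cys", "His", "Gln", "Asn", "Lys",
                     "Asp", "Glu", "Met", "Trp")

.grantham_upper <- c(
  # Ser
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
  # Arg
       102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
  # Leu
             98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
  # Pro
                  38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
  # Thr
                       58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
  # Ala
                            64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
  # Val
                                109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
  # Gly
                                     135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
  # Ile
                                           21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
  # Phe
                                                22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
  # Tyr
                                                    194,  83,  99, 143,  85, 160, 122,  36,  37,
  # Cys
                                                         174, 154, 139, 202, 154, 170, 196, 215,
  # His
                                                               24,  68,  32,  81,  40,  87, 115,
  # Gln
                                                                    46,  53,  61,  29, 101, 130,
  # Asn
                                                                         94,  23,  42, 142, 174,
  # Lys
                                                                             101,  56,  95, 110,
  # Asp
                                                                                   45, 160, 181,
  # Glu
                                                                                       126, 152,
  # Met
                                                                                             67
)

.build_grantham <- function() {
  n <- length(.grantham_order)
  m <- matrix(0, n, n, dimnames = list(.grantham_order, .grantham_order))
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- .grantham_upper[k]
      m[j, i] <- .grantham_upper[k]
      k <- k + 1L
    }
  }
  m
}

GRANTHAM_MATRIX <- .build_grantham()

#' Normalize an amino-acid token to its three-letter code
#'
#' Accepts one-letter or three-letter residue codes (any capitalisation) and
#' the non-residue tokens `fs`, `Ter`, `del`, `dup`, which are passed through
#' in canonical form. `*` is treated as `Ter`.
#'
#' @param token character scalar.
#' @return the canonical three-letter (or special) token.
#' @export
normalize_aa_token <- function(token) {
  if (length(token) != 1L || is.na(token) || !nzchar(token)) {
    stop("amino-acid token must be a non-empty string", call. = FALSE)
  }
  low <- tolower(token)
  specials <- c(fs = "fs", ter = "Ter", del = "del", dup = "dup", `*` = "Ter")
  if (low %in% names(specials)) {
    return(unname(specials[low]))
  }
  if (nchar(token) == 1L) {
    up <- toupper(token)
    if (up %in% names(AA_ONE_TO_THREE)) {
      return(unname(AA_ONE_TO_THREE[up]))
    }
    stop(sprintf("unknown one-letter amino-acid code: '%s'", token),
         call. = FALSE)
  }
  cap <- paste0(toupper(substr(low, 1, 1)), substr(low, 2, nchar(low)))
  if (cap %in% c(AA_THREE, "Sec")) {
    return(cap)
  }
  stop(sprintf("unknown amino-acid token: '%s'", token), call. = FALSE)
}

#' Ordinal code of an amino-acid token
#'
#' Maps a residue token to its integer code. The `ref` dialect covers the 21
#' residues (including selenocysteine); the `mut` dialect additionally maps
#' the non-substitution consequences `fs`, `Ter`, `del` and `dup` to the
#' shared code 22.
#'
#' @param token residue token (one- or three-letter) or special token.
#' @param dialect `"ref"` or `"mut"`.
#' @return integer code.
#' @export
encode_aa_index <- function(token, dialect = c("ref", "mut")) {
  dialect <- match.arg(dialect)
  tok <- normalize_aa_token(token)
  map <- if (dialect == "ref") AA_INDEX_REF else AA_INDEX_MUT
  if (!tok %in% names(map)) {
    stop(sprintf("token '%s' has no code in the '%s' dialect", tok, dialect),
         call. = FALSE)
  }
  unname(as.integer(map[tok]))
}

#' Side-chain polarity code of a token
#'
#' Returns the polarity-group encoding of a residue, or 0.0 for the sentinel
#' tokens (`Ter`, `dup`, `del`, `fs`, `p.?`, `p.(=)`, `NA`).
#'
#' @param token residue or sentinel token.
#' @return numeric polarity code.
#' @export
chemical_value <- function(token) {
  if (length(token) != 1L || is.na(token)) {
    return(0.0)
  }
  if (token %in% names(AA_CHEMICAL)) {
    return(unname(AA_CHEMICAL[token]))
  }
  tok <- tryCatch(normalize_aa_token(token), error = function(e) NULL)
  if (is.null(tok) || !tok %in% names(AA_CHEMICAL)) {
    stop(sprintf("no polarity code for token '%s'", token), call. = FALSE)
  }
  unname(AA_CHEMICAL[tok])
}

#' Grantham distance between two residues
#'
#' Physico-chemical distance between two amino acids from the embedded
#' published matrix. Identical residues score 0; distinct pairs lie in
#' \[5, 215\]. When either token is not one of the 20 standard residues
#' (frameshift, stop, deletion, selenocysteine, or a missing token) the
#' sentinel -1 is returned, marking the score "not applicable".
#'
#' @param aa1,aa2 residue tokens (one- or three-letter) or special tokens.
#' @return numeric distance, 0, or -1.
#' @export
grantham_distance <- function(aa1, aa2) {
  norm_or_na <- function(x) {
    if (length(x) != 1L || is.na(x) || identical(x, "NA")) {
      return(NA_character_)
    }
    tryCatch(normalize_aa_token(x), error = function(e) NA_character_)
  }
  t1 <- norm_or_na(aa1)
  t2 <- norm_or_na(aa2)
  if (is.na(t1) || is.na(t2) ||
      !(t1 %in% .grantham_order) || !(t2 %in% .grantham_order)) {
    return(-1)
  }
  unname(GRANTHAM_MATRIX[t1, t2])
}
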