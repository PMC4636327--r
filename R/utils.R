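#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rbinom runif setNames aggregate cor
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Watson-Crick complement of a character vector of DNA strings (position-wise).
dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Reverse complement: complement of the reversed string.
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Fast reverse complement for large character vectors via Biostrings.
dna_revcomp_many <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split DNA strings into a character matrix (rows = sequences). All inputs
# must share one length.
seq_char_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) > 1) stop("sequences have unequal lengths")
  if (length(x) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

# Integer encoding A=1 C=2 G=3 T=4; gaps ('-','.') = 0; anything else = 5.
BASE_CODE <- local({
  v <- rep(5L, 256)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v[utf8ToInt("-")] <- 0L; v[utf8ToInt(".")] <- 0L
  v
})

seq_to_int <- function(s) {
  BASE_CODE[utf8ToInt(s)]
}

# Rows = sequences, equal lengths required.
seq_int_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) > 1) stop("sequences have unequal lengths")
  if (length(x) == 0 || n == 0) {
    return(matrix(integer(0), nrow = length(x), ncol = if (length(n)) n else 0))
  }
  matrix(BASE_CODE[unlist(lapply(x, utf8ToInt), use.names = FALSE)],
         nrow = length(x), ncol = n, byrow = TRUE)
}

int_to_seq <- function(v) {
  lut <- c("-", "A", "C", "G", "T", "N")
  paste(lut[v + 1L], collapse = "")
}

# Distinct k-mers of a sequence as 0-based 2-bit codes in [0, 4^k).
# Windows containing non-ACGT characters are dropped.
encode_kmers <- function(s, k = 8L) {
  v <- seq_to_int(s) - 1L             # A=0 C=1 G=2 T=3; gaps -> -1; N -> 4
  n <- length(v)
  if (n < k) return(integer(0))
  valid <- v >= 0L & v <= 3L
  code <- numeric(n - k + 1L)
  ok <- rep(TRUE, n - k + 1L)
  mult <- 4^((k - 1L):0)
  for (j in seq_len(k)) {
    idx <- j:(n - k + j)
    code <- code + v[idx] * mult[j]
    ok <- ok & valid[idx]
  }
  unique(as.integer(code[ok]))
}

# Uniform random DNA string(s).
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute `n_sub` randomly chosen positions of `s` with a different base.
mutate_positions <- function(s, n_sub) {
  if (n_sub == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
  }
  paste(v, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
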