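# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the guide oracle is a position-by-position loop, the
# alignment oracle a plain affine-gap dynamic program, the classifier oracle
# an enumerated rule table.

# brute-force glocal (global-in-read, local-in-reference) affine-gap optimal
# score; gap of length L costs open + L * ext
bruteGlocalScore <- function(read, ref, match = 5, mismatch = 4,
                             open = 10, ext = 0.5) {
  p <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e18
  # state matrices over (i = read prefix, j = ref position consumed last)
  M <- matrix(NEG, m + 1, n + 1)   # last column: substitution
  X <- matrix(NEG, m + 1, n + 1)   # last column: gap in read (ref consumed)
  Y <- matrix(NEG, m + 1, n + 1)   # last column: gap in ref (read consumed)
  start <- rep(0, n + 1)           # free start anywhere in the reference
  for (i in 1:m) {
    for (j in 0:n) {
      jj <- j + 1
      if (j >= 1) {
        sub <- if (p[i] == s[j]) match else -mismatch
        prev <- if (i == 1) start[jj - 1] else
          max(M[i, jj - 1], X[i, jj - 1], Y[i, jj - 1])
        M[i + 1, jj] <- prev + sub
        X[i + 1, jj] <- max(M[i + 1, jj - 1] - open - ext,
                            X[i + 1, jj - 1] - ext,
                            Y[i + 1, jj - 1] - open - ext)
      }
      Y[i + 1, jj] <- if (i == 1) start[jj] - open - ext else
        max(M[i, jj] - open - ext, Y[i, jj] - ext, X[i, jj] - open - ext)
    }
  }
  max(M[m + 1, ], X[m + 1, ], Y[m + 1, ])
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

revcompChar <- function(x) {
  paste(rev(unname(.comp[strsplit(x, "")[[1]]])), collapse = "")
}

# independent NGG scan: plain loop, no regex shared with the implementation
guideScanOracle <- function(seqchar, variant_offset = NA,
                            require_overlap = FALSE,
                            strands = c("both", "top", "bottom")) {
  strands <- match.arg(strands)
  L <- nchar(seqchar)
  res <- list()
  scan <- function(sq, strand) {
    ch <- strsplit(sq, "")[[1]]
    for (i in seq_len(L)) {
      if (i < 21 || i + 2 > L) next
      if (ch[i + 1] == "G" && ch[i + 2] == "G") {
        if (strand == "+") {
          st <- as.integer(i - 20); en <- as.integer(i - 1)
        } else {
          st <- as.integer(L - i + 2); en <- as.integer(L - i + 21)
        }
        res[[length(res) + 1]] <<- data.frame(
          protospacer = substr(sq, i - 20, i - 1),
          pam = substr(sq, i, i + 2), strand = strand,
          start = st, end = en, stringsAsFactors = FALSE)
      }
    }
  }
  if (strands %in% c("both", "top")) scan(seqchar, "+")
  if (strands %in% c("both", "bottom")) scan(revcompChar(seqchar), "-")
  g <- if (length(res)) do.call(rbind, res) else
    data.frame(protospacer = character(0), pam = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  if (require_overlap && nrow(g)) {
    g <- g[g$start <= variant_offset & g$end >= variant_offset, , drop = FALSE]
  }
  g <- g[order(g$start, g$strand), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# enumerated classification rule: marker state x net indel length
classifierOracle <- function(marker, L_values) {
  if (marker %in% c("other", "uncovered")) return("discarded")
  if (marker == "wt") return("wt")
  if (length(L_values) == 0) return("mutant_unedited")
  L <- sum(L_values)
  out_of_frame <- abs(L) >= 1 && abs(L) <= 8 && (L %% 3) != 0
  if (out_of_frame) "mutant_edited" else "mutant_excluded"
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
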