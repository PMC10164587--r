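# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# normalise a nucleotide string to the internal DNA alphabet (uppercase, U -> T)
norm_seq <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("sequence contains characters outside {A,C,G,T,U,N}: %s",
                  substr(x[bad][1], 1, 40)))
  }
  x
}

# display alphabet for structure work (T -> U)
as_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

revcomp <- function(x) {
  chartr("ACGTU", "TGCAA", x) |>
    vapply(function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "") |>
    unname()
}

# median with even counts resolved to the lower middle value (keeps integers)
med_lo <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

# centred moving average, width w (odd); edges use the available values
moving_average <- function(x, w = 5) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(x[idx], na.rm = TRUE)
  }, numeric(1))
}

# strict interior local extrema of a numeric vector; plateaus use their centre
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "max") x <- -x
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] < x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j <= n - 1 && x[j + 1] > x[j]) {
        out <- c(out, floor((i + j) / 2))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
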