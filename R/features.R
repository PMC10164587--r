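#' Annotate bulges and internal loops along a duplex stem
#'
#' Walks consecutive base pairs of a duplex structure. An inter-pair gap with
#' unpaired nucleotides on exactly one arm and length 1 is a bulge; any other
#' non-empty gap (longer on one arm, or unpaired on both arms) is an internal
#' loop. Sizes are recorded per arm together with the stem position (index of
#' the preceding pair).
#'
#' @param structure A `duplex_structure`.
#' @return Tibble with `kind` (`bulge` / `internal_loop`), `arm1_len`,
#'   `arm2_len`, `stem_position`.
#' @export
annotate_loops <- function(structure) {
  p <- arrange(structure$pairs, .data$i)
  empty <- tibble(kind = character(), arm1_len = integer(),
                  arm2_len = integer(), stem_position = integer())
  if (nrow(p) < 2) return(empty)
  g1 <- p$i[-1] - head(p$i, -1) - 1L
  g2 <- head(p$j, -1) - p$j[-1] - 1L # j decreases along the stem
  keep <- g1 + g2 > 0
  if (!any(keep)) return(empty)
  tibble(kind = if_else(xor(g1[keep] == 0, g2[keep] == 0) &
                          (g1[keep] + g2[keep]) == 1L,
                        "bulge", "internal_loop"),
         arm1_len = g1[keep], arm2_len = g2[keep],
         stem_position = which(keep))
}

#' Classify the symmetry of a duplex structure
#'
#' `perfect` duplexes have no bulges or internal loops. `symmetric` duplexes
#' have every loop element identically sized on both arms at the same stem
#' position (the strict all-mirrored rule). Remaining duplexes are
#' `asymmetric_with_bulge` when at least one bulge is present, else
#' `asymmetric_no_bulge`.
#'
#' @param structure A `duplex_structure`.
#' @return One of `perfect`, `symmetric`, `asymmetric_no_bulge`,
#'   `asymmetric_with_bulge`.
#' @export
classify_symmetry <- function(structure) {
  loops <- annotate_loops(structure)
  if (nrow(loops) == 0) return("perfect")
  if (all(loops$arm1_len == loops$arm2_len)) return("symmetric")
  if (any(loops$kind == "bulge")) return("asymmetric_with_bulge")
  "asymmetric_no_bulge"
}

#' Fraction of loop elements mirrored on both arms
#'
#' Per-element symmetry: the fraction of bulges/internal loops whose two arm
#' sizes are equal (1 for perfect or fully symmetric duplexes).
#'
#' @param structure A `duplex_structure`.
#' @return Numeric fraction in \[0, 1\].
#' @export
symmetry_fraction <- function(structure) {
  loops <- annotate_loops(structure)
  if (nrow(loops) == 0) return(1)
  mean(loops$arm1_len == loops$arm2_len)
}

#' Composition summary of a duplex structure
#'
#' @param structure A `duplex_structure`.
#' @return One-row tibble: `au_pair_pct` (% of pairs that are A:U or U:A),
#'   `gc_pct` (% G:C), `gu_pct` (% G:U), `percent_paired` (% of all arm
#'   residues in pairs), `n_pairs`, `longest_stem_segment` (longest run of
#'   contiguous pairs with no intervening unpaired nucleotide on either arm).
#' @export
composition <- function(structure) {
  p <- arrange(structure$pairs, .data$i)
  n <- nrow(p)
  if (n == 0) {
    return(tibble(au_pair_pct = 0, gc_pct = 0, gu_pct = 0,
                  percent_paired = 0, n_pairs = 0L,
                  longest_stem_segment = 0L))
  }
  b1 <- substring(structure$arm1, p$i, p$i)
  b2 <- substring(structure$arm2, p$j, p$j)
  pairs <- paste0(b1, b2)
  au <- pairs %in% c("AU", "UA")
  gc <- pairs %in% c("GC", "CG")
  gu <- pairs %in% c("GU", "UG")
  contig <- if (n == 1) TRUE else
    c(TRUE, (p$i[-1] == head(p$i, -1) + 1L) & (p$j[-1] == head(p$j, -1) - 1L))
  runs <- rle(cumsum(!contig))
  tibble(au_pair_pct = 100 * mean(au), gc_pct = 100 * mean(gc),
         gu_pct = 100 * mean(gu),
         percent_paired = 100 * (2 * n) /
           (nchar(structure$arm1) + nchar(structure$arm2)),
         n_pairs = n, longest_stem_segment = max(runs$lengths))
}

#' Classify intra-transcript duplex spans
#'
#' Span classes follow the printed boundaries: short-range below 25 nt,
#' medium-range 25-100 nt inclusive, long-range above 100 nt. Duplexes
#' tagged as derived pass their tag through. Inter-transcript duplexes have
#' no span and raise an error unless tagged derived.
#'
#' @param duplexes Duplex tibble with `span` (and optionally a `sources` or
#'   `derived` marker).
#' @return `duplexes` with a `span_class` column.
#' @export
classify_spans <- function(duplexes) {
  d <- as_tibble(duplexes)
  derived <- if ("derived" %in% names(d)) d$derived
             else if ("sources" %in% names(d)) grepl("derived", d$sources)
             else rep(FALSE, nrow(d))
  if (any(is.na(d$span) & !derived)) {
    abort("span undefined for non-derived (inter-transcript) duplex")
  }
  mutate(d, span_class = dplyr::case_when(
    derived ~ "derived",
    .data$span < 25 ~ "short",
    .data$span <= 100 ~ "medium",
    TRUE ~ "long"))
}

#' Structure feature table for a duplex atlas
#'
#' Computes the minimum-free-energy structure of every duplex from its arm
#' sequences and summarises composition, loop architecture, symmetry and
#' (optionally) the shuffled-control energy.
#'
#' @param duplexes Duplex tibble (arm intervals per row).
#' @param reference Reference tibble.
#' @param model Energy model (see [duplex_mfe()]).
#' @param control_iterations Shuffle iterations for the control energy
#'   (0 disables; the study default is 100).
#' @return Feature tibble keyed by `duplex_id`.
#' @export
duplex_features <- function(duplexes, reference,
                            model = "nearest_neighbour",
                            control_iterations = 0) {
  seqs <- setNames(reference$sequence, reference$transcript_id)
  rows <- lapply(seq_len(nrow(duplexes)), function(k) {
    d <- duplexes[k, ]
    a1 <- substr(seqs[[d$prox_tx]], d$prox_start + 1, d$prox_end)
    a2 <- substr(seqs[[d$dist_tx]], d$dist_start + 1, d$dist_end)
    ds <- duplex_mfe(a1, a2, model = model)
    comp <- composition(ds)
    loops <- annotate_loops(ds)
    ctrl <- if (control_iterations > 0) {
      control_energy(a1, a2, n_iter = control_iterations, model = model)
    } else NA_real_
    tibble(duplex_id = d$duplex_id, energy = ds$energy,
           control_energy = ctrl,
           normalised_energy = normalised_energy(ds),
           n_bulges = sum(loops$kind == "bulge"),
           n_internal_loops = sum(loops$kind == "internal_loop"),
           symmetry_class = classify_symmetry(ds),
           symmetry_fraction = symmetry_fraction(ds),
           dot_bracket = ds$dot_bracket) %>%
      dplyr::bind_cols(comp)
  })
  bind_rows(rows)
}

#' Fit a univariate Gaussian mixture to duplex spans by EM
#'
#' Expectation-maximisation with k-means++ style initialisation. The
#' log-likelihood is asserted to be non-decreasing across iterations;
#' components are reported sorted by decreasing mean. Degenerate data
#' (all values equal) collapse to a single component with the sigma floor.
#'
#' @param spans Numeric vector of spans.
#' @param k Number of components (default 2).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param sigma_floor Lower bound on component standard deviations.
#' @return An object of class `span_mixture` with elements `lambda`, `mu`,
#'   `sigma`, `loglik` (final), `loglik_trace`, `n`, `k`, `iterations`,
#'   `converged`. Supports [tidy()], [glance()] and `autoplot()`.
#' @export
fit_span_mixture <- function(spans, k = 2, max_iter = 500, tol = 1e-6,
                             sigma_floor = 1e-3) {
  x <- as.numeric(spans[!is.na(spans)])
  n <- length(x)
  if (n < 2 * k) abort("need at least 2k observations")
  if (length(unique(x)) == 1) {
    fit <- list(lambda = c(1, rep(0, k - 1)), mu = rep(x[1], k),
                sigma = rep(sigma_floor, k), loglik = NA_real_,
                loglik_trace = numeric(0), n = n, k = k, iterations = 0L,
                converged = TRUE)
    class(fit) <- "span_mixture"
    return(fit)
  }
  # k-means++ style seeding of the component means
  mu <- x[sample.int(n, 1)]
  while (length(mu) < k) {
    d2 <- vapply(x, function(v) min((v - mu)^2), numeric(1))
    mu <- c(mu, x[sample.int(n, 1, prob = d2 / sum(d2))])
  }
  sigma <- rep(max(sd(x) / k, sigma_floor), k)
  lambda <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    dens <- vapply(seq_len(k), function(j) {
      lambda[j] * dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_d))
    if (length(ll_trace) > 0 && ll < ll_old - 1e-8) {
      abort("EM log-likelihood decreased") # internal consistency guard
    }
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    lambda <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- pmax(sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk),
                  sigma_floor)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  ord <- order(mu, decreasing = TRUE)
  fit <- list(lambda = lambda[ord], mu = mu[ord], sigma = sigma[ord],
              loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
              n = n, k = k, iterations = iter, converged = converged)
  class(fit) <- "span_mixture"
  fit
}

#' @export
print.span_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (k = %d, n = %d, logLik = %.2f)\n",
              x$k, x$n, x$loglik))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: lambda = %.3f, mu = %.1f, sigma = %.1f\n",
                j, x$lambda[j], x$mu[j], x$sigma[j]))
  }
  invisible(x)
}

#' @export
tidy.span_mixture <- function(x, ...) {
  tibble(component = seq_len(x$k), lambda = x$lambda, mu = x$mu,
         sigma = x$sigma)
}

#' @export
glance.span_mixture <- function(x, ...) {
  tibble(k = x$k, n = x$n, logLik = x$loglik, iterations = x$iterations,
         converged = x$converged)
}
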