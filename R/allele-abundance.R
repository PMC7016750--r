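#' Per-allele read likelihoods
#'
#' Each mate is placed at its best ungapped offset (both strands) on each
#' trimmed allele; with `m` mismatches over aligned length `L` the mate
#' likelihood is `(error_rate/3)^m * (1-error_rate)^(L-m)`, and mates
#' multiply. A read pair whose best alignment exceeds `max_mismatch_rate`
#' mismatches per aligned base on *both* alleles fails the score gate and is
#' discarded (reported, not an error). `N` bases mismatch everything, so a
#' read with `N` at a diagnostic site scores both alleles equally there.
#'
#' @param r1,r2 character vectors of mate sequences (equal length).
#' @param pair trimmed `allele_pair`.
#' @param error_rate assumed per-base miscall probability (in `(0, 1)`).
#' @param max_mismatch_rate score gate: maximum tolerated mismatch fraction
#'   on the better allele.
#' @return matrix with columns `surface` and `cave` of per-pair
#'   log-likelihoods, one row per retained read pair; attributes `retained`
#'   (logical per input pair) and `n_discarded`.
#' @export
read_allele_likelihood <- function(r1, r2, pair, error_rate = 0.005,
                                   max_mismatch_rate = 0.1) {
  stopifnot(inherits(pair, "allele_pair"), length(r1) == length(r2))
  if (error_rate <= 0 || error_rate >= 1)
    stop("error_rate must be in (0, 1)")
  if (length(r1) == 0L) {
    out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("surface", "cave")))
    attr(out, "retained") <- logical(0)
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  len <- nchar(r1) + nchar(r2)
  # counts exact up to the gate; clamped beyond it (see pair_allele_mismatches)
  cap <- as.integer(ceiling(max_mismatch_rate * max(len)))
  mm <- pair_allele_mismatches(r1, r2, pair$surface_seq, pair$cave_seq, cap)
  mm_s <- mm[, "surface"]
  mm_c <- mm[, "cave"]
  # NA = unalignable (read longer than allele)
  best_rate <- pmin(mm_s, mm_c, na.rm = FALSE) / len
  retained <- !is.na(mm_s) & !is.na(mm_c) & best_rate <= max_mismatch_rate
  log_e <- log(error_rate / 3)
  log_m <- log1p(-error_rate)
  ll <- cbind(surface = mm_s[retained] * log_e + (len[retained] - mm_s[retained]) * log_m,
              cave = mm_c[retained] * log_e + (len[retained] - mm_c[retained]) * log_m)
  attr(ll, "retained") <- retained
  attr(ll, "n_discarded") <- sum(!retained)
  ll
}

#' EM estimation of allele-specific abundance (THETA)
#'
#' Treats each retained read pair's allele of origin as latent. The E-step
#' assigns each pair fractionally in proportion to `theta_a * likelihood_a`;
#' the M-step sets `theta_a` proportional to `(fractional count_a + prior) /
#' effective length_a` (a Dirichlet-style posterior mean). Iterates until
#' the largest theta change falls below `tol` or `max_iter` is reached.
#' Reads scoring equally on both alleles stay in with 50/50 fractional
#' assignment.
#'
#' @param reads a `read_pairs` object (or list with `r1`, `r2`).
#' @param pair trimmed `allele_pair`.
#' @param error_rate,max_mismatch_rate passed to [read_allele_likelihood()].
#' @param prior_pseudocount Dirichlet pseudocount added per allele.
#' @param tol convergence threshold on `max |delta theta|`.
#' @param max_iter iteration cap (warning + `converged = FALSE` beyond it).
#' @param fragment_mean mean fragment length, for the effective length
#'   `max(1, allele length - fragment_mean + 1)` used by theta and FPKM.
#' @param library_size total mapped fragments for FPKM scaling; defaults to
#'   the number of retained pairs (single-gene usage).
#' @return object of class `theta_estimate`: list with `gene_id`, `theta`
#'   (named surface/cave, summing to 1), `expected_fragments` (fractional
#'   counts summing to the retained read count), `fpkm`, `n_retained`,
#'   `n_discarded`, `converged`, `n_iter`, `loglik` (trace), and `defined`
#'   (`FALSE` when no reads were retained).
#' @export
estimate_theta <- function(reads, pair, error_rate = 0.005,
                           max_mismatch_rate = 0.1,
                           prior_pseudocount = 1.0, tol = 1e-6,
                           max_iter = 500L, fragment_mean = 250,
                           library_size = NULL) {
  ll <- read_allele_likelihood(reads$r1, reads$r2, pair, error_rate,
                               max_mismatch_rate)
  n <- nrow(ll)
  eff_len <- pmax(1, nchar(c(surface = pair$surface_seq,
                             cave = pair$cave_seq)) - fragment_mean + 1)
  if (n == 0L) {
    return(structure(list(
      gene_id = pair$gene_id,
      theta = c(surface = NA_real_, cave = NA_real_),
      expected_fragments = c(surface = 0, cave = 0),
      fpkm = c(surface = 0, cave = 0),
      n_retained = 0L, n_discarded = attr(ll, "n_discarded"),
      converged = TRUE, n_iter = 0L, loglik = numeric(0), defined = FALSE),
      class = "theta_estimate"))
  }
  # per-read scaling for numerical stability
  base <- apply(ll, 1, max)
  lik <- exp(ll - base)
  theta <- c(surface = 0.5, cave = 0.5)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    num <- sweep(lik, 2, theta, "*")
    rowsum_ <- rowSums(num)
    loglik <- c(loglik, sum(log(rowsum_) + base))
    w <- num / rowsum_
    counts <- colSums(w)
    theta_new <- (counts + prior_pseudocount) / eff_len
    theta_new <- theta_new / sum(theta_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) {
      warning("EM did not converge in ", max_iter, " iterations for gene ",
              pair$gene_id)
      break
    }
  }
  num <- sweep(lik, 2, theta, "*")
  counts <- colSums(num / rowSums(num))
  if (is.null(library_size)) library_size <- n
  fpkm <- counts / (eff_len / 1e3) / (library_size / 1e6)
  structure(list(
    gene_id = pair$gene_id,
    theta = stats::setNames(theta, c("surface", "cave")),
    expected_fragments = stats::setNames(counts, c("surface", "cave")),
    fpkm = stats::setNames(fpkm, c("surface", "cave")),
    n_retained = n, n_discarded = attr(ll, "n_discarded"),
    converged = converged, n_iter = iter, loglik = loglik, defined = TRUE),
    class = "theta_estimate")
}

#' Estimate THETA for many genes across hybrid replicates
#'
#' Runs [estimate_theta()] per gene and replicate. Reads are routed to genes
#' by the `gene:rest` prefix of their FASTQ identifiers (as emitted by
#' [generate_study()]); the per-replicate library size used for FPKM is the
#' total number of retained pairs across genes.
#'
#' @param pairs named list of trimmed `allele_pair`s.
#' @param replicates list of `read_pairs` objects (one per hybrid
#'   replicate), each with an `id` field.
#' @param ... passed to [estimate_theta()].
#' @return data frame with columns `gene_id`, `allele`, `replicate`,
#'   `expected_fragments`, `fpkm`, `theta`, `defined`.
#' @export
estimate_theta_study <- function(pairs, replicates, ...) {
  rows <- list()
  for (rep_i in seq_along(replicates)) {
    rp <- replicates[[rep_i]]
    gene_of_read <- sub(":.*$", "", rp$id)
    ests <- lapply(names(pairs), function(g) {
      sel <- gene_of_read == g
      estimate_theta(list(r1 = rp$r1[sel], r2 = rp$r2[sel]), pairs[[g]], ...)
    })
    lib <- sum(vapply(ests, `[[`, integer(1), "n_retained"))
    for (est in ests) {
      scale <- if (est$n_retained > 0L && lib > 0L) est$n_retained / lib else 1
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = est$gene_id,
        allele = c("surface", "cave"),
        replicate = rep_i,
        expected_fragments = unname(est$expected_fragments),
        fpkm = unname(est$fpkm * scale),
        theta = unname(est$theta),
        defined = est$defined,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
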