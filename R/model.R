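#' Overlap model parameters
#'
#' The generative model of read cloud composition: a metagenome of `G_count`
#' genomes, each modelled as a discrete collection of exactly `N_g`
#' fragments; genome `i` is drawn with geometrically decaying probability
#' proportional to `2^-i` (microbial communities are dominated by 1-2
#' species with a long tail) and a fragment uniformly within the genome. A
#' read cloud is a selection of `N_f` such fragments, each fractionally
#' covered by reads at rate `C_r`.
#'
#' @param N_f fragments per read cloud.
#' @param N_g fragments per genome.
#' @param G_count number of genomes.
#' @param C_r fractional read coverage of a fragment (0 < C_r <= 1).
#' @return An object of class `overlap_model_params`.
#' @export
overlap_model_params <- function(N_f = 5L, N_g = 100L, G_count = 10L,
                                 C_r = 0.1) {
  stopifnot(N_f >= 1, N_g >= 1, G_count >= 1, C_r > 0, C_r <= 1)
  structure(list(N_f = as.integer(N_f), N_g = as.integer(N_g),
                 G_count = as.integer(G_count), C_r = C_r),
            class = "overlap_model_params")
}

#' Fragment collision probability p_f
#'
#' Probability that two independently drawn fragments are the same fragment
#' class. Under the geometric genome-abundance model the probability that two
#' draws hit the same genome tends to 1/2 as the number of genomes grows, and
#' conditional on the same genome the fragment collides with probability
#' `1/N_g`, giving the closed form `p_f = 1/(2*N_g)`.
#'
#' With a finite `n_genomes`, the truncated-and-renormalized geometric
#' distribution gives the exact same-genome probability
#' `sum(q_i^2)` with `q_i = 2^-i / (1 - 2^-n)`; this variant is what a
#' finite simulation actually samples and is exposed for comparing
#' Monte-Carlo runs against the analytic overlap distribution.
#'
#' @param N_g fragments per genome.
#' @param n_genomes number of genomes; `Inf` (default) gives the limiting
#'   closed form `1/(2*N_g)`.
#' @return Collision probability (scalar).
#' @examples
#' fragment_collision_prob(100)        # 0.005
#' fragment_collision_prob(100, 10)    # what a 10-genome simulation samples
#' @export
fragment_collision_prob <- function(N_g, n_genomes = Inf) {
  stopifnot(N_g >= 1, n_genomes >= 1)
  if (is.infinite(n_genomes)) return(1 / (2 * N_g))
  i <- seq_len(n_genomes)
  q <- 2^(-i) / (1 - 2^(-n_genomes))
  sum(q^2) / N_g
}

#' Closed-form distribution of shared fragments between two read clouds
#'
#' For two read clouds of `N_f` fragments each, with pairwise fragment
#' collision probability `p_f`:
#'
#' * `X0 = (1 - p_f)^(N_f^2)` — none of the `N_f^2` fragment pairs collide;
#' * `X1 = 2*N_f*(1-(1-p_f)^N_f)*(1-p_f)^(N_f*(N_f-1)) -
#'    N_f^2*p_f*(1-p_f)^(N_f^2-1)` — exactly one fragment on either side is
#'   involved in a collision (the subtracted term corrects the
#'   double-counted one-to-one case);
#' * `X2plus = 1 - X0 - X1`.
#'
#' @param N_f fragments per read cloud.
#' @param p_f fragment collision probability, e.g. from
#'   [fragment_collision_prob()].
#' @return Named numeric vector `c(X0=, X1=, X2plus=)`.
#' @examples
#' overlap_distribution(5, fragment_collision_prob(100))
#' @export
overlap_distribution <- function(N_f, p_f) {
  stopifnot(N_f >= 1, p_f >= 0, p_f < 1)
  N_f <- as.numeric(N_f)
  X0 <- (1 - p_f)^(N_f^2)
  X1 <- 2 * N_f * (1 - (1 - p_f)^N_f) * (1 - p_f)^(N_f * (N_f - 1)) -
    N_f^2 * p_f * (1 - p_f)^(N_f^2 - 1)
  c(X0 = X0, X1 = X1, X2plus = 1 - X0 - X1)
}

#' Ratio of single to multiple fragment overlaps
#'
#' `X1 / X2plus`: how much more likely two read clouds are to share exactly
#' one fragment than more than one. Large values mean spurious multi-fragment
#' connections between clouds are rare, which is what makes cloud-overlap
#' evidence usable for deconvolution.
#'
#' @inheritParams overlap_distribution
#' @return Scalar ratio; `Inf` when `X2plus` is zero.
#' @export
single_to_multi_ratio <- function(N_f, p_f) {
  x <- overlap_distribution(N_f, p_f)
  if (x[["X2plus"]] <= 0) return(Inf)
  x[["X1"]] / x[["X2plus"]]
}

#' Monte-Carlo verification of the overlap distribution
#'
#' Draws pairs of read clouds under the generative model — genome index from
#' a truncated geometric distribution `2^-i` over `1..G_count`
#' (renormalized), fragment uniform over `1..N_g`, `N_f` independent draws
#' per cloud (duplicate fragment classes within one cloud are allowed, as in
#' the model) — and tabulates the number of distinct fragment classes shared
#' by each pair.
#'
#' Because the truncated geometric is what is actually sampled, the matching
#' analytic distribution is [overlap_distribution()] evaluated at
#' `fragment_collision_prob(N_g, G_count)`, not at the `1/(2*N_g)` limit;
#' the limit form overstates the same-genome probability relative to any
#' finite geometric sample.
#'
#' @param params an [overlap_model_params()] object.
#' @param n_pairs number of read cloud pairs to draw.
#' @param seed integer RNG seed.
#' @return Named numeric vector `c(X0=, X1=, X2plus=)` of empirical
#'   proportions, with attribute `n_pairs`.
#' @export
simulate_overlap_distribution <- function(params, n_pairs = 1e5, seed = 1L) {
  stopifnot(inherits(params, "overlap_model_params"), n_pairs >= 1)
  n_pairs <- as.integer(n_pairs)
  set.seed(seed)
  i <- seq_len(params$G_count)
  gprob <- 2^(-i) / sum(2^(-i))
  ndraw <- 2L * n_pairs * params$N_f
  genome <- sample.int(params$G_count, ndraw, replace = TRUE, prob = gprob)
  frag <- sample.int(params$N_g, ndraw, replace = TRUE)
  class_id <- (genome - 1L) * params$N_g + frag
  # layout: pair-major blocks of 2*N_f draws (cloud A then cloud B)
  dim(class_id) <- c(params$N_f, 2L, n_pairs)
  shared <- vapply(seq_len(n_pairs), function(p) {
    length(intersect(class_id[, 1L, p], class_id[, 2L, p]))
  }, integer(1))
  out <- c(X0 = mean(shared == 0L), X1 = mean(shared == 1L),
           X2plus = mean(shared >= 2L))
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Information-theoretic recoverability bound
#'
#' Treats deconvolution of one read cloud as a community recovery problem:
#' reads are linked with probability `p` when they come from the same
#' fragment (true positive rate) and `q` when from different fragments
#' (false positive rate). Asymptotically, accurate clustering requires
#'
#' `N_r / log(N_r) * (p - q)^2 > N_f`
#'
#' so the returned value is the maximum number of fragments that a cloud of
#' `N_r` reads can hope to resolve. Natural log is used; the bound is
#' asymptotic in graphs of thousands of nodes while real deconvolution
#' graphs are often small, so it is an optimistic guide, not a guarantee.
#'
#' @param N_r number of reads in the cloud (>= 2).
#' @param p same-fragment link probability.
#' @param q different-fragment link probability (`q < p`).
#' @return Scalar bound (maximum recoverable `N_f`).
#' @export
recovery_bound <- function(N_r, p, q) {
  stopifnot(N_r >= 2, p >= 0, p <= 1, q >= 0, q <= 1)
  N_r / log(N_r) * (p - q)^2
}

#' Is a read cloud recoverable?
#'
#' Predicate form of [recovery_bound()]: can a cloud of `N_r` reads over
#' `N_f` fragments be accurately deconvolved given link probabilities
#' `p`, `q`?
#'
#' @inheritParams recovery_bound
#' @param N_f number of fragments in the cloud.
#' @return Logical.
#' @export
is_recoverable <- function(N_r, N_f, p, q) {
  recovery_bound(N_r, p, q) > N_f
}

#' Expected shared coverage points of two overlapping fragments
#'
#' Each fragment is fractionally covered by reads at rate `C_r`, so two long
#' fragments overlapping the same genomic region are expected to be covered
#' by reads of both at a rate of `C_r^2` per unit of overlapped length.
#' Cloud pairs sharing tokens far above this expectation indicate repetitive
#' or conserved sequence; the `max_shared` bound of [deconv_params()] is the
#' corresponding filter.
#'
#' @param C_r fractional coverage (0 < C_r <= 1).
#' @return `C_r^2`.
#' @export
expected_overlap_points <- function(C_r) {
  stopifnot(C_r > 0, C_r <= 1)
  C_r^2
}
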