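# Desk-scale simulation of neutral and sweep-bearing chromosomes.
#
# Neutral background: sequential Markov coalescent (SMC'), whose marginal
# genealogies are exact coalescent trees. Selective phase: forward
# Wright-Fisher on the whole population with a single beneficial mutation,
# conditioned by rejection sampling on the requested population frequency at
# sampling time. Defaults emulate a constant-size diploid population with
# population-scaled mutation and recombination totals of 1,000 over a 1 Mb
# chromosome (theta = rho, i.e. 0.001 per bp in population-scaled units).

#' Simulation parameters
#'
#' @param N diploid effective population size.
#' @param L chromosome length in bp.
#' @param mu,r per-bp per-generation mutation and recombination rates;
#'   defaults give population-scaled totals `4*N*mu*L = 4*N*r*L = 1000`
#'   (so theta = rho, at 0.001 per bp in scaled units).
#' @param n haploid sample size (must be even; sequences are sampled as
#'   `n/2` diploid individuals).
#' @param selection `NULL` for neutral evolution, or a list with elements
#'   `ns2` (the scaled selection coefficient `2*N*s`, default 500), `h`
#'   (dominance, default 1 = fully dominant), `position` (bp, default the
#'   chromosome center), and either `target_freq` (population frequency of
#'   the beneficial allele at sampling, e.g. 0.5/0.7/0.9, with tolerance
#'   `tol`, default 0.02) or `fixed_since` (scaled time in units of `4*N`
#'   generations the allele has been fixed before sampling, e.g. 0.01).
#' @param seed master seed; per-chromosome seeds are derived from it by a
#'   fixed counter scheme so chromosomes are independently reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(N = 500, L = 1e6, mu = NULL, r = NULL, n = 200,
                       selection = NULL, seed = 1L) {
  if (is.null(mu)) mu <- 1000 / (4 * N * L)
  if (is.null(r)) r <- 1000 / (4 * N * L)
  stopifnot(mu >= 0, r >= 0, N >= 2, n >= 2, n <= 2 * N)
  if (n %% 2 != 0) stop("sample size n must be even (diploid individuals)")
  if (!is.null(selection)) {
    sel_defaults <- list(ns2 = 500, h = 1, position = L / 2,
                         target_freq = NULL, fixed_since = NULL, tol = 0.02)
    selection <- utils::modifyList(sel_defaults, selection)
    if (is.null(selection$target_freq) && is.null(selection$fixed_since))
      selection$target_freq <- 0.7
    if (!is.null(selection$target_freq))
      stopifnot(selection$target_freq > 0, selection$target_freq <= 1)
  }
  structure(list(N = N, L = L, mu = mu, r = r, n = as.integer(n),
                 selection = selection, seed = as.integer(seed)),
            class = "sim_params")
}

# round continuous positions to distinct integer bp (minimal right shift)
.positions_to_bp <- function(pos) {
  p <- pmax(round(pos), 1)
  shifted <- 0L
  if (length(p) > 1) for (i in 2:length(p)) {
    if (p[i] <= p[i - 1]) {
      p[i] <- p[i - 1] + 1
      shifted <- shifted + 1L
    }
  }
  structure(as.numeric(p), n_shifted = shifted)
}

.chrom_seeds <- function(master, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master)
  sample.int(2147483646L, k)
}

.sim_haploset <- function(pos, mat, chrom, L) {
  bp <- .positions_to_bp(pos)
  haploset(mat, positions = as.numeric(bp), chrom = chrom, phased = TRUE,
           ancestral = rep(0L, nrow(mat)), extent = c(1, L))
}

.new_genome <- function(haps, truth) {
  structure(list(haps = haps, truth = truth), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$haps), "chromosome(s),",
      sum(vapply(x$haps, n_markers, integer(1))), "markers,",
      sum(x$truth$status != "neutral"), "under selection\n")
  invisible(x)
}

#' Simulate a neutrally evolving genome
#'
#' Independent chromosomes sampled from a neutral coalescent with
#' recombination (SMC'); mutations follow the infinite-sites model with
#' uniform placement, alleles are polarized (0 = ancestral) and phased.
#'
#' @param params a [sim_params()] with `selection = NULL`.
#' @param n_chromosomes number of independent chromosomes.
#' @return A `sim_genome`: a list of [haploset]s plus a truth table.
#' @export
simulate_neutral <- function(params, n_chromosomes = 20) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$selection))
    stop("simulate_neutral() requires selection = NULL")
  theta <- 4 * params$N * params$mu * params$L
  rho <- 4 * params$N * params$r * params$L
  exp_S <- theta * sum(1 / seq_len(params$n - 1))
  if (exp_S < 10)
    warning("expected segregating sites ", signif(exp_S, 3),
            " < 10; statistics will be unreliable")
  seeds <- .chrom_seeds(params$seed, n_chromosomes)
  haps <- vector("list", n_chromosomes)
  for (i in seq_len(n_chromosomes)) {
    set.seed(seeds[i])
    sim <- cpp_sim_neutral(params$n, params$L, theta, rho)
    haps[[i]] <- .sim_haploset(sim$pos, sim$mat, paste0("chr", i), params$L)
  }
  names(haps) <- paste0("chr", seq_len(n_chromosomes))
  truth <- data.frame(chrom = names(haps), pos = NA_real_,
                      pop_freq = NA_real_, sample_freq = NA_real_,
                      status = "neutral")
  .new_genome(haps, truth)
}

#' Simulate chromosomes carrying a single hard sweep
#'
#' Each chromosome evolves neutrally except for one beneficial mutation at
#' the configured position (the center by default). The population is drawn
#' from the neutral generator, the mutation is injected and the population is
#' evolved forward under Wright-Fisher dynamics with selection, recombination
#' and new mutation until the beneficial allele's population frequency is
#' within `tol` of `target_freq` (trajectories are rejection-sampled:
#' extinction or overshoot restarts the attempt), or -- with `fixed_since` --
#' until fixation plus the requested number of extra generations.
#'
#' @inheritParams simulate_neutral
#' @param max_attempts bound on trajectory rejections per chromosome.
#' @return A `sim_genome` with the selected position, realized population and
#'   sample frequencies, and sweep status in its truth table.
#' @export
simulate_sweep <- function(params, n_chromosomes = 100, max_attempts = 1000) {
  stopifnot(inherits(params, "sim_params"))
  sel <- params$selection
  if (is.null(sel)) stop("simulate_sweep() requires a selection setting")
  theta <- 4 * params$N * params$mu * params$L
  rho <- 4 * params$N * params$r * params$L
  s <- sel$ns2 / (2 * params$N)
  fixed_extra <- if (!is.null(sel$fixed_since))
    as.integer(round(sel$fixed_since * 4 * params$N)) else -1L
  target <- if (!is.null(sel$target_freq)) sel$target_freq else 1
  seeds <- .chrom_seeds(params$seed, n_chromosomes)
  haps <- vector("list", n_chromosomes)
  truth <- vector("list", n_chromosomes)
  for (i in seq_len(n_chromosomes)) {
    set.seed(seeds[i])
    sim <- cpp_sim_sweep(2L * params$N, params$L, theta, rho,
                         params$mu * params$L, params$r * params$L,
                         params$n, s, sel$h, sel$position, target, sel$tol,
                         fixed_extra, max_attempts, 40L * params$N)
    chrom <- paste0("chr", i)
    haps[[i]] <- .sim_haploset(sim$pos, sim$mat, chrom, params$L)
    # bp coordinate of the selected site after rounding
    bp_sel <- round(sel$position)
    k <- which(abs(sim$pos - sel$position) < 1e-9)
    if (length(k) == 1) bp_sel <- haps[[i]]$positions[k]
    truth[[i]] <- data.frame(chrom = chrom, pos = bp_sel,
                             pop_freq = sim$pop_freq,
                             sample_freq = sim$sample_freq,
                             status = if (fixed_extra >= 0) "fixed" else
                               "ongoing")
  }
  names(haps) <- paste0("chr", seq_len(n_chromosomes))
  .new_genome(haps, do.call(rbind, truth))
}

#' Simulate a symmetric two-population split
#'
#' An ancestral population is drawn from the neutral generator, duplicated,
#' and both copies drift independently (no migration) for
#' `split_time * 4 * N` generations before sampling -- the null model for the
#' cross-population statistics.
#'
#' @inheritParams simulate_neutral
#' @param split_time split age in units of `4*N` generations.
#' @return A list with two `sim_genome`s, `pop1` and `pop2`.
#' @export
simulate_split <- function(params, n_chromosomes = 1, split_time = 0.05) {
  stopifnot(inherits(params, "sim_params"))
  theta <- 4 * params$N * params$mu * params$L
  rho <- 4 * params$N * params$r * params$L
  gens <- as.integer(round(split_time * 4 * params$N))
  seeds <- .chrom_seeds(params$seed, n_chromosomes)
  h1 <- h2 <- vector("list", n_chromosomes)
  for (i in seq_len(n_chromosomes)) {
    set.seed(seeds[i])
    sim <- cpp_sim_split(2L * params$N, params$L, theta, rho,
                         params$mu * params$L, params$r * params$L,
                         params$n, gens)
    chrom <- paste0("chr", i)
    h1[[i]] <- .sim_haploset(sim$pop1$pos, sim$pop1$mat, chrom, params$L)
    h2[[i]] <- .sim_haploset(sim$pop2$pos, sim$pop2$mat, chrom, params$L)
  }
  names(h1) <- names(h2) <- paste0("chr", seq_len(n_chromosomes))
  truth <- data.frame(chrom = names(h1), pos = NA_real_, pop_freq = NA_real_,
                      sample_freq = NA_real_, status = "neutral")
  list(pop1 = .new_genome(h1, truth), pop2 = .new_genome(h2, truth))
}
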