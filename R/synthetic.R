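#' Sample a ground-truth regulatory network
#'
#' Draws a sparse signed regulator-to-target network: every ordered
#' (regulator, other gene) pair receives an edge independently with
#' probability `avg_out_degree / (n_genes - 1)`, so a regulator's expected
#' out-degree is `avg_out_degree`. Each edge is a repressor (sign -1) with
#' probability `repressor_fraction` and carries a positive strength drawn
#' uniformly from [0.5, 2].
#'
#' @param n_genes number of genes.
#' @param n_regulators number of regulator genes (the first `n_regulators`
#'   ids); must be at least 1 and at most `n_genes`.
#' @param avg_out_degree expected out-degree per regulator; at most
#'   `n_genes - 1`.
#' @param repressor_fraction probability that an edge is repressing.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A [gt_network].
#' @export
sample_ground_truth_network <- function(n_genes, n_regulators,
                                        avg_out_degree,
                                        repressor_fraction = 0.3,
                                        seed = 1) {
  if (n_genes < 2) stop("'n_genes' must be at least 2")
  if (n_regulators < 1 || n_regulators > n_genes)
    stop("'n_regulators' must be in [1, n_genes]")
  if (avg_out_degree <= 0 || avg_out_degree > n_genes - 1)
    stop("impossible degree demand: 'avg_out_degree' must be in (0, n_genes - 1]")
  if (repressor_fraction < 0 || repressor_fraction > 1)
    stop("'repressor_fraction' must be in [0, 1]")
  genes <- sprintf("G%04d", seq_len(n_genes))
  regulators <- genes[seq_len(n_regulators)]
  p <- avg_out_degree / (n_genes - 1)
  with_seed(seed, {
    src <- rep(regulators, each = n_genes - 1L)
    tgt <- unlist(lapply(regulators, function(r) setdiff(genes, r)),
                  use.names = FALSE)
    keep <- runif(length(src)) < p
    src <- src[keep]
    tgt <- tgt[keep]
    sign <- ifelse(runif(length(src)) < repressor_fraction, -1, 1)
    strength <- runif(length(src), 0.5, 2)
    gt_network(genes, regulators,
               data.frame(source = src, target = tgt, sign = sign,
                          strength = strength, stringsAsFactors = FALSE))
  })
}

#' Simulate time-course expression driven by a ground-truth network
#'
#' Regulators follow smooth exogenous trajectories (softplus of a random
#' cubic in scaled time, mimicking developmental trends). A target's
#' expression at time step k (k >= 2) is a softplus response to the
#' signed, strength-weighted sum of its regulators' standardized realized
#' expression at step k - 1 within the same replicate, so up-regulation
#' propagates monotonically; the first time point uses the regulator
#' state at that same point.
#'
#' Noise is replicate-structured: each (gene, replicate) pair carries a
#' persistent Gaussian offset (seed-to-seed biological variability that
#' follows a replicate across the whole course) plus independent
#' measurement noise per value, both with standard deviation `noise_sd`.
#' The regulator's realized fluctuation around its mean trend propagates
#' to its targets within the same sample (transcriptional response is
#' fast relative to the days-apart sampling grid), while the
#' developmental mean trend propagates with a one-step delay; this is
#' what makes the parent regulator statistically identifiable from
#' samples. Values are clamped at zero, giving non-negative FPKM-like
#' data.
#'
#' @param net a [gt_network] with at least one edge.
#' @param time_points numeric vector of at least 2 time points (days after
#'   pollination). Default mirrors a 0/2/4/6/7/8 DAP seed sampling design.
#' @param n_replicates replicates per time point (default 3).
#' @param noise_sd standard deviation of both noise components (>= 0;
#'   default 1, a substantial noise level relative to the typical
#'   expression scale of a few units).
#' @param gain coupling gain multiplying the signed regulator drive
#'   (default 4): regulation is strong relative to intrinsic noise.
#' @param seed integer seed.
#' @return An [expression_set] over `net$genes`.
#' @export
simulate_time_course <- function(net, time_points = c(0, 2, 4, 6, 7, 8),
                                 n_replicates = 3, noise_sd = 1,
                                 gain = 4, seed = 1) {
  if (!inherits(net, "gt_network")) stop("'net' must be a gt_network")
  if (nrow(net$edges) == 0L) stop("network has no edges")
  if (length(time_points) < 2L) stop("at least 2 time points required")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be positive")
  genes <- net$genes
  ng <- length(genes)
  tt <- length(time_points)
  nrep <- as.integer(n_replicates)
  ncol_out <- tt * nrep
  col_time <- rep(seq_len(tt), each = nrep)   # time index of each column
  col_rep <- rep(seq_len(nrep), times = tt)   # replicate index
  s <- if (diff(range(time_points)) > 0)
    2 * (time_points - min(time_points)) / diff(range(time_points)) - 1
  else rep(0, tt)

  # soft response: softplus with a softened knee so moderate repression
  # does not saturate immediately at zero
  resp_fun <- function(x) 2 * softplus(x / 2)

  with_seed(seed, {
    # exogenous regulator mean trajectories
    nr <- length(net$regulators)
    co <- matrix(rnorm(4 * nr, mean = c(1, 0, 0, 0), sd = c(1, 1.5, 1, 1)),
                 nrow = 4)
    traj <- matrix(0, nrow = nr, ncol = tt,
                   dimnames = list(net$regulators, NULL))
    for (r in seq_len(nr))
      traj[r, ] <- resp_fun(co[1, r] + co[2, r] * s + co[3, r] * s^2 +
                              co[4, r] * s^3)
    baseline <- resp_fun(rnorm(ng, mean = 2, sd = 1))
    names(baseline) <- genes
    # replicate-structured noise: persistent per (gene, replicate) offset
    # plus per-value measurement noise
    delta <- matrix(if (noise_sd > 0) rnorm(ng * nrep, sd = noise_sd)
                    else 0, nrow = ng, ncol = nrep,
                    dimnames = list(genes, NULL))
    eps <- matrix(if (noise_sd > 0) rnorm(ng * ncol_out, sd = noise_sd)
                  else 0, nrow = ng, ncol = ncol_out,
                  dimnames = list(genes, NULL))

    vals <- matrix(0, nrow = ng, ncol = ncol_out,
                   dimnames = list(genes, NULL))
    is_reg <- genes %in% net$regulators
    for (g in genes[is_reg])
      vals[g, ] <- pmax(traj[g, col_time] + delta[g, col_rep] + eps[g, ], 0)

    # regulator inputs, standardized by the mean-trajectory scale and
    # split into the slow mean trend and the realized fluctuation
    zmean <- matrix(0, nrow = nr, ncol = tt,
                    dimnames = list(net$regulators, NULL))
    zfluc <- matrix(0, nrow = nr, ncol = ncol_out,
                    dimnames = list(net$regulators, NULL))
    for (g in net$regulators) {
      sc <- sd(traj[g, ])
      if (sc == 0) sc <- 1
      zmean[g, ] <- (traj[g, ] - mean(traj[g, ])) / sc
      zfluc[g, ] <- (vals[g, ] - traj[g, col_time]) / sc
    }
    lag_t <- c(1L, seq_len(tt - 1L))  # previous time index (first maps to itself)

    targets <- split(net$edges, net$edges$target)
    for (g in genes[!is_reg]) {
      ed <- targets[[g]]
      if (is.null(ed)) {
        resp <- rep(baseline[g], ncol_out)
      } else {
        sw <- ed$sign * ed$strength
        drive_mean <- colSums(zmean[ed$source, , drop = FALSE] * sw)
        drive_fluc <- colSums(zfluc[ed$source, , drop = FALSE] * sw)
        resp <- resp_fun(baseline[g] +
                           gain * (drive_mean[lag_t][col_time] + drive_fluc))
      }
      vals[g, ] <- pmax(resp + delta[g, col_rep] + eps[g, ], 0)
    }
    expression_set(vals,
                   time_dap = time_points[col_time],
                   replicate = col_rep)
  })
}

#' Simulate two-condition overdispersed counts with planted enrichment
#'
#' Generates negative-binomial counts (mean/dispersion parameterization,
#' log-normal baseline means) for an endosperm vs whole-seed contrast.
#' Exactly `n_enriched` randomly chosen genes have their endosperm-group
#' mean multiplied by `2^effect_log2fc`; the chosen genes are recorded as
#' ground truth.
#'
#' @param n_genes number of genes.
#' @param n_enriched number of truly enriched genes (<= `n_genes`).
#' @param effect_log2fc log2 fold change applied to enriched genes in the
#'   endosperm group (positive).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be positive.
#' @param n_reps_per_group samples per group (default 7, matching a
#'   seven-replicate endosperm design).
#' @param seed integer seed.
#' @return A [count_set] with `truth` flags.
#' @export
simulate_two_condition_counts <- function(n_genes, n_enriched,
                                          effect_log2fc = 2,
                                          dispersion = 0.1,
                                          n_reps_per_group = 7,
                                          seed = 1) {
  if (n_enriched > n_genes) stop("'n_enriched' cannot exceed 'n_genes'")
  if (n_enriched < 0) stop("'n_enriched' must be non-negative")
  if (effect_log2fc <= 0) stop("'effect_log2fc' must be positive")
  if (dispersion <= 0) stop("'dispersion' must be positive")
  if (n_reps_per_group < 1) stop("'n_reps_per_group' must be positive")
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    base_mu <- rlnorm(n_genes, meanlog = 4, sdlog = 1)
    enriched <- rep(FALSE, n_genes)
    if (n_enriched > 0) enriched[sample.int(n_genes, n_enriched)] <- TRUE
    mu_endo <- base_mu * ifelse(enriched, 2^effect_log2fc, 1)
    nb_draw <- function(mu, n_rep) {
      size <- 1 / dispersion
      m <- matrix(0, nrow = length(mu), ncol = n_rep)
      for (j in seq_len(n_rep)) {
        m[, j] <- if (size > 1e8) rpois(length(mu), mu)
        else rnbinom(length(mu), size = size, mu = mu)
      }
      m
    }
    counts <- cbind(nb_draw(mu_endo, n_reps_per_group),
                    nb_draw(base_mu, n_reps_per_group))
    rownames(counts) <- genes
    group <- rep(c("endosperm", "whole_seed"), each = n_reps_per_group)
    colnames(counts) <- sprintf("%s_%d", group,
                                rep(seq_len(n_reps_per_group), 2))
    names(enriched) <- genes
    count_set(counts, group, truth = enriched)
  })
}
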