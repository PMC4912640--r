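#' MCMC configuration for the sparse Lotka-Volterra model
#'
#' Presets: `"desk"` (4 chains x 20,000 iterations, burn-in 10,000,
#' thin 10) for routine desk-scale runs, `"paper"` (10 chains x 5e6,
#' burn-in 2e6, thin 50) for publication-grade final runs, and
#' `"test"` (2 chains x 4,000, burn-in 2,000, thin 4) for quick checks.
#' Any field can be overridden.
#'
#' @param preset `"desk"`, `"paper"` or `"test"`.
#' @param chains,iterations,burn_in,thin MCMC protocol overrides.
#' @param inclusion_prob prior inclusion probability P of each directed
#'   interaction (default 0.1).
#' @param prior_r_variance variance of the Normal(0, .) prior on
#'   intrinsic growth rates (default 10).
#' @param prior_k_rate rate of the Exponential prior on carrying
#'   capacities (default 1).
#' @param pi_sd prior s.d. of the per-replicate depth offsets Pi_m
#'   (default 100).
#' @param sigma_prior_sd scale of the half-Normal prior on
#'   process-noise s.d. (default 1).
#' @param slab_variance variance of the Normal slab on included
#'   interaction coefficients; `NULL` (default) scales the slab per
#'   edge from the pilot run as `slab_multiplier` times the pilot
#'   posterior variance (an SSVS-style information scale), which keeps
#'   null-link inclusion probabilities near the prior P.
#' @param slab_multiplier multiplier for the pilot-scaled slab.
#' @param pilot_iterations length of the unconstrained pilot run that
#'   sets the Gibbs-variable-selection pseudo-priors.
#' @param replicate_order policy passed to [order_replicates()].
#' @param seed integer seed.
#' @return an `lv_config` list.
#' @export
lv_config <- function(preset = c("desk", "paper", "test"),
                      chains = NULL, iterations = NULL, burn_in = NULL,
                      thin = NULL, inclusion_prob = 0.1,
                      prior_r_variance = 10, prior_k_rate = 1,
                      pi_sd = 100, sigma_prior_sd = 1, slab_variance = NULL,
                      slab_multiplier = 3,
                      pilot_iterations = 2000,
                      replicate_order = "sorted_id", seed = 1) {
  preset <- match.arg(preset)
  def <- switch(preset,
                desk = list(chains = 4, iterations = 20000, burn_in = 10000, thin = 10),
                paper = list(chains = 10, iterations = 5e6, burn_in = 2e6, thin = 50),
                test = list(chains = 2, iterations = 4000, burn_in = 2000, thin = 4))
  cfg <- list(preset = preset,
              chains = chains %||% def$chains,
              iterations = iterations %||% def$iterations,
              burn_in = burn_in %||% def$burn_in,
              thin = thin %||% def$thin,
              inclusion_prob = inclusion_prob,
              prior_r_variance = prior_r_variance,
              prior_k_rate = prior_k_rate,
              pi_sd = pi_sd,
              sigma_prior_sd = sigma_prior_sd,
              slab_variance = slab_variance,
              slab_multiplier = slab_multiplier,
              pilot_iterations = pilot_iterations,
              replicate_order = replicate_order,
              seed = seed)
  if (cfg$burn_in >= cfg$iterations) stop("burn_in must be < iterations")
  if (cfg$inclusion_prob <= 0 || cfg$inclusion_prob >= 1)
    stop("inclusion_prob must lie in (0, 1)")
  structure(cfg, class = "lv_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the posterior of the sparse Lotka-Volterra model
#'
#' Markov chain Monte Carlo for the replicate-series model
#' n_i,m = n_i,m-1 + r_i (1 - (N_i,m-1 - sum_j g_ij a_ij N_j,m-1)/k_i)
#' + eps_i,m, y_i,m ~ Poisson(exp(n_i,m + log N_m + Pi_m)), with priors
#' r_i ~ N(0, 10), k_i ~ Exp(1), g_ij ~ Bernoulli(P), a_ij | g_ij = 1 ~
#' N(0, slab), sigma_i ~ half-N(1), Pi_m ~ N(0, 100^2).  Interaction
#' coefficients are switched in and out of the likelihood by Gibbs
#' variable selection; when excluded, a_ij is drawn from a pseudo-prior
#' centred on a short unconstrained pilot run (all g = 1) so the
#' indicator can re-enter without a reversible-jump move.
#'
#' The updates are: exact conjugate Gaussian draws for r_i and for each
#' row of included a_ij; exact Bernoulli draws for g_ij; elementwise
#' random-walk Metropolis on the latent states n_i,m in an
#' odd/even-replicate checkerboard (within one species and parity the
#' full conditionals factorize); adaptive random-walk Metropolis on
#' log k_i, log sigma_i and Pi_m.
#'
#' @param core a `core_set`, [count_table] (replicates x OTUs), or
#'   integer matrix (OTUs x replicates).
#' @param cfg an [lv_config].
#' @return an `lv_posterior`; see [lv_summary()].
#' @export
sample_posterior <- function(core, cfg = lv_config()) {
  y <- if (inherits(core, "core_set")) {
    ord <- order_replicates(core, cfg$replicate_order, seed = cfg$seed)
    t(core$counts$counts[ord, , drop = FALSE])
  } else if (inherits(core, "count_table")) {
    ord <- order_replicates(core, cfg$replicate_order, seed = cfg$seed)
    t(core$counts[ord, , drop = FALSE])
  } else {
    as.matrix(core)
  }
  S <- nrow(y); M <- ncol(y)
  if (S < 2) stop("need at least 2 core OTUs to model interactions")
  if (M < 10) stop("need at least 10 replicates")
  otus <- rownames(y) %||% sprintf("Otu%03d", seq_len(S))
  o <- log(pmax(colSums(y), 1))

  # directed edge list (i, j): effect of OTU j on the growth of OTU i
  ei <- as.vector(row(matrix(0, S, S)))[as.vector(row(matrix(0, S, S)) != col(matrix(0, S, S)))]
  ej <- as.vector(col(matrix(0, S, S)))[as.vector(row(matrix(0, S, S)) != col(matrix(0, S, S)))]
  E <- length(ei)

  pilot <- withr::with_seed(derive_seed(cfg$seed, 0L), {
    run_lv_chain(y, o, cfg, pseudo = NULL, gvs = FALSE,
                 n_iter = cfg$pilot_iterations,
                 n_burn = cfg$pilot_iterations %/% 2, thin = 2,
                 ei = ei, ej = ej, slab_var = rep(1, E))
  })
  pm <- colMeans(pilot$alpha)
  psd <- pmax(apply(pilot$alpha, 2, stats::sd), 0.05)
  pseudo <- list(mean = pm, var = psd^2)
  slab_var <- if (is.null(cfg$slab_variance)) {
    cfg$slab_multiplier * psd^2
  } else {
    rep(cfg$slab_variance, E)
  }

  chains <- lapply(seq_len(cfg$chains), function(ch) {
    withr::with_seed(derive_seed(cfg$seed, ch), {
      run_lv_chain(y, o, cfg, pseudo = pseudo, gvs = TRUE,
                   n_iter = cfg$iterations, n_burn = cfg$burn_in,
                   thin = cfg$thin, ei = ei, ej = ej, jitter = ch > 1,
                   slab_var = slab_var)
    })
  })

  g_all <- do.call(rbind, lapply(chains, `[[`, "g"))
  a_all <- do.call(rbind, lapply(chains, `[[`, "alpha"))
  pip <- colMeans(g_all)
  amean_active <- vapply(seq_len(E), function(e) {
    sel <- g_all[, e] == 1
    if (any(sel)) mean(a_all[sel, e]) else 0
  }, 0)

  diag <- lv_diagnostics(chains, S, E)
  structure(list(chains = chains, S = S, M = M, otu_ids = otus,
                 ei = ei, ej = ej, cfg = cfg, pseudo = pseudo,
                 pip = pip, alpha_mean = colMeans(a_all),
                 alpha_mean_active = amean_active,
                 gamma_jumps = Reduce(`+`, lapply(chains, `[[`, "jumps")),
                 diagnostics = diag),
            class = "lv_posterior")
}

#' @export
print.lv_posterior <- function(x, ...) {
  cat(sprintf("lv_posterior: S = %d OTUs, M = %d replicates, %d chains x %d draws\n",
              x$S, x$M, length(x$chains), nrow(x$chains[[1]]$r)))
  cat(sprintf("  mean included links %.2f of %d candidates; max R-hat %.3f%s\n",
              mean(rowSums(do.call(rbind, lapply(x$chains, `[[`, "g")))),
              length(x$ei), x$diagnostics$max_rhat,
              if (isTRUE(x$diagnostics$rhat_warn)) " (warning: > 1.1)" else ""))
  invisible(x)
}

#' Posterior summary table
#'
#' @param post an `lv_posterior`.
#' @return data.frame with one row per OTU-level parameter and per
#'   candidate interaction (posterior mean, inclusion probability).
#' @export
lv_summary <- function(post) {
  r_all <- do.call(rbind, lapply(post$chains, `[[`, "r"))
  k_all <- do.call(rbind, lapply(post$chains, `[[`, "k"))
  s_all <- do.call(rbind, lapply(post$chains, `[[`, "sigma"))
  otu <- data.frame(
    parameter = c(paste0("r[", post$otu_ids, "]"),
                  paste0("k[", post$otu_ids, "]"),
                  paste0("sigma[", post$otu_ids, "]")),
    mean = c(colMeans(r_all), colMeans(k_all), colMeans(s_all)),
    sd = c(apply(r_all, 2, stats::sd), apply(k_all, 2, stats::sd),
           apply(s_all, 2, stats::sd)),
    stringsAsFactors = FALSE)
  inter <- data.frame(
    parameter = sprintf("alpha[%s<-%s]", post$otu_ids[post$ei],
                        post$otu_ids[post$ej]),
    mean = post$alpha_mean_active,
    inclusion_prob = post$pip,
    gamma_jumps = post$gamma_jumps,
    stringsAsFactors = FALSE)
  list(parameters = otu, interactions = inter)
}

# One MCMC chain.  gvs = FALSE runs the unconstrained pilot (all
# indicators fixed at 1, slab prior only).
run_lv_chain <- function(y, o, cfg, pseudo, gvs, n_iter, n_burn, thin,
                         ei, ej, slab_var, jitter = FALSE) {
  S <- nrow(y); M <- ncol(y); E <- length(ei)
  vr <- cfg$prior_r_variance
  P <- cfg$inclusion_prob
  emat <- matrix(0L, S, S); emat[cbind(ei, ej)] <- seq_len(E)
  pi_var <- cfg$pi_sd^2
  sig_pr <- cfg$sigma_prior_sd

  # init
  n <- log(y + 0.5) - rep(o, each = S)
  r <- rep(0.5, S); if (jitter) r <- r + stats::rnorm(S, 0, 0.2)
  k <- pmax(rowMeans(exp(n)), 1e-4)
  if (jitter) k <- k * exp(stats::rnorm(S, 0, 0.3))
  sig <- rep(0.3, S)
  Pi <- rep(0, M)
  alpha <- matrix(0, S, S)
  if (!gvs) g <- matrix(1, S, S) else g <- matrix(0, S, S)
  diag(g) <- 0; diag(alpha) <- 0
  if (gvs && jitter) {
    g[cbind(ei, ej)] <- stats::rbinom(E, 1, P)
    alpha[cbind(ei, ej)] <- stats::rnorm(E, pseudo$mean, sqrt(pseudo$var))
  }
  A <- alpha * g
  Ncur <- exp(n)
  wmat <- Ncur - A %*% Ncur # effective density per (i, m)

  ty <- colSums(y)
  odd <- seq(1, M, by = 2); even <- seq(2, M, by = 2)

  step_n <- rep(0.15, S); step_k <- rep(0.3, S)
  step_s <- rep(0.4, S); step_pi <- 0.05
  acc_n <- integer(S); acc_k <- integer(S); acc_s <- integer(S); acc_pi <- 0
  batch <- 50L; tries <- 0L

  keep <- floor((n_iter - n_burn) / thin)
  out <- list(r = matrix(NA_real_, keep, S), k = matrix(NA_real_, keep, S),
              sigma = matrix(NA_real_, keep, S),
              alpha = matrix(NA_real_, keep, E), g = matrix(0L, keep, E),
              Pi = matrix(NA_real_, keep, M))
  jumps <- integer(E)
  g_prev <- g[cbind(ei, ej)]
  kept <- 0L

  for (it in seq_len(n_iter)) {
    tries <- tries + 1L
    eo <- exp(o + Pi)

    ## --- latent states: per-species odd/even checkerboard MH ---
    for (i in seq_len(S)) {
      Ji <- which(A[, i] != 0) # rows whose dynamics read N_i
      Ji <- Ji[Ji != i]
      for (ms in list(odd, even)) {
        nc <- n[i, ms]
        np <- nc + step_n[i] * stats::rnorm(length(ms))
        dN <- exp(np) - exp(nc)
        dl <- y[i, ms] * (np - nc) - dN * eo[ms]
        # target term: process for m >= 2, initial prior for m = 1
        mst <- ms[ms >= 2]
        if (length(mst)) {
          f <- n[i, mst - 1] + r[i] * (1 - wmat[i, mst - 1] / k[i])
          sel <- match(mst, ms)
          dl[sel] <- dl[sel] +
            ((nc[sel] - f)^2 - (np[sel] - f)^2) / (2 * sig[i]^2)
        }
        if (1 %in% ms) {
          s1 <- match(1, ms)
          dl[s1] <- dl[s1] + ((nc[s1] - log(k[i]))^2 - (np[s1] - log(k[i]))^2) / 2
        }
        # source term: columns m + 1 read N_i,m through the dynamics
        msf <- ms[ms < M]
        if (length(msf)) {
          self <- match(msf, ms)
          w0 <- wmat[i, msf]
          f0 <- nc[self] + r[i] * (1 - w0 / k[i])
          f1 <- np[self] + r[i] * (1 - (w0 + dN[self]) / k[i])
          nn <- n[i, msf + 1]
          dl[self] <- dl[self] + ((nn - f0)^2 - (nn - f1)^2) / (2 * sig[i]^2)
          for (j in Ji) {
            ecur <- n[j, msf + 1] - (n[j, msf] + r[j] * (1 - wmat[j, msf] / k[j]))
            delta <- (r[j] / k[j]) * A[j, i] * dN[self]
            dl[self] <- dl[self] + (ecur^2 - (ecur - delta)^2) / (2 * sig[j]^2)
          }
        }
        acc <- log(stats::runif(length(ms))) < dl
        if (any(acc)) {
          macc <- ms[acc]
          n[i, macc] <- np[acc]
          Ncur[i, macc] <- exp(np[acc])
          dacc <- dN[acc]
          wmat[i, macc] <- wmat[i, macc] + dacc
          if (length(Ji))
            wmat[Ji, macc] <- wmat[Ji, macc, drop = FALSE] -
              A[Ji, i] %o% dacc
          acc_n[i] <- acc_n[i] + sum(acc)
        }
      }
    }

    ## --- depth offsets Pi_m: vectorized MH (columns independent) ---
    qn <- colSums(Ncur)
    pip_prop <- Pi + step_pi * stats::rnorm(M)
    dl <- ty * (pip_prop - Pi) - (exp(pip_prop) - exp(Pi)) * exp(o) * qn -
      (pip_prop^2 - Pi^2) / (2 * pi_var)
    acc <- log(stats::runif(M)) < dl
    Pi[acc] <- pip_prop[acc]
    acc_pi <- acc_pi + mean(acc)

    ## --- growth rates r_i: exact conjugate Gaussian ---
    d <- n[, 2:M, drop = FALSE] - n[, 1:(M - 1), drop = FALSE]
    X <- 1 - wmat[, 1:(M - 1), drop = FALSE] / k
    prec <- rowSums(X^2) / sig^2 + 1 / vr
    mu <- (rowSums(X * d) / sig^2) / prec
    r <- mu + stats::rnorm(S) / sqrt(prec)

    ## --- carrying capacities k_i: MH on log k ---
    for (i in seq_len(S)) {
      lk <- log(k[i]); lkp <- lk + step_k[i] * stats::rnorm(1)
      kp <- exp(lkp)
      w <- wmat[i, 1:(M - 1)]
      e0 <- d[i, ] - r[i] * (1 - w / k[i])
      e1 <- d[i, ] - r[i] * (1 - w / kp)
      dl <- sum(e0^2 - e1^2) / (2 * sig[i]^2) +
        ((n[i, 1] - lk)^2 - (n[i, 1] - lkp)^2) / 2 +
        cfg$prior_k_rate * (k[i] - kp) + (lkp - lk)
      if (log(stats::runif(1)) < dl) { k[i] <- kp; acc_k[i] <- acc_k[i] + 1L }
    }

    ## --- process noise sigma_i: MH on log sigma ---
    X <- 1 - wmat[, 1:(M - 1), drop = FALSE] / k
    res <- d - r * X
    sse <- rowSums(res^2)
    for (i in seq_len(S)) {
      ls <- log(sig[i]); lsp <- ls + step_s[i] * stats::rnorm(1)
      sp <- exp(lsp)
      dl <- -(M - 1) * (lsp - ls) - sse[i] * (1 / (2 * sp^2) - 1 / (2 * sig[i]^2)) -
        (sp^2 - sig[i]^2) / (2 * sig_pr^2) + (lsp - ls)
      if (log(stats::runif(1)) < dl) { sig[i] <- sp; acc_s[i] <- acc_s[i] + 1L }
    }

    ## --- interactions: GVS indicator flips, then conjugate alpha rows ---
    Nprev <- Ncur[, 1:(M - 1), drop = FALSE]
    for (i in seq_len(S)) {
      zfac <- r[i] / k[i]
      dstar <- d[i, ] - r[i] + zfac * Nprev[i, ]
      others <- setdiff(seq_len(S), i)
      arow <- alpha[i, ]; grow <- g[i, ]
      ecur <- dstar - zfac * as.vector((arow * grow)[others] %*% Nprev[others, , drop = FALSE])
      if (gvs) {
        for (j in others) {
          cj <- zfac * arow[j] * Nprev[j, ]
          e1 <- ecur - (1 - grow[j]) * cj
          e0 <- ecur + grow[j] * cj
          eidx <- emat[i, j]
          logit <- log(P / (1 - P)) +
            stats::dnorm(arow[j], 0, sqrt(slab_var[eidx]), log = TRUE) -
            stats::dnorm(arow[j], pseudo$mean[eidx], sqrt(pseudo$var[eidx]),
                         log = TRUE) +
            sum(e0^2 - e1^2) / (2 * sig[i]^2)
          gnew <- stats::rbinom(1, 1, 1 / (1 + exp(-logit)))
          if (gnew != grow[j]) {
            grow[j] <- gnew
            ecur <- if (gnew == 1) e1 else e0
          }
        }
        g[i, ] <- grow
      }
      act <- which(grow == 1)
      if (length(act)) {
        Z <- zfac * t(Nprev[act, , drop = FALSE])
        precm <- crossprod(Z) / sig[i]^2 +
          diag(1 / slab_var[emat[i, act]], length(act))
        ch <- chol(precm)
        mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, dstar) / sig[i]^2))
        arow[act] <- mu + backsolve(ch, stats::rnorm(length(act)))
      }
      inact <- setdiff(others, act)
      if (gvs && length(inact)) {
        eidx <- emat[i, inact]
        arow[inact] <- stats::rnorm(length(inact), pseudo$mean[eidx],
                                    sqrt(pseudo$var[eidx]))
      }
      alpha[i, ] <- arow
      A[i, ] <- arow * grow
      wmat[i, ] <- Ncur[i, ] - as.vector(A[i, ] %*% Ncur)
    }

    ## --- adaptation during burn-in ---
    if (it <= n_burn && it %% batch == 0) {
      gain <- exp(1 / sqrt(it / batch))
      rate_n <- acc_n / (batch * M)
      step_n <- step_n * ifelse(rate_n > 0.35, gain, 1 / gain)
      rate_k <- acc_k / batch
      step_k <- step_k * ifelse(rate_k > 0.35, gain, 1 / gain)
      rate_s <- acc_s / batch
      step_s <- step_s * ifelse(rate_s > 0.35, gain, 1 / gain)
      step_pi <- step_pi * if (acc_pi / batch > 0.35) gain else 1 / gain
      acc_n[] <- 0L; acc_k[] <- 0L; acc_s[] <- 0L; acc_pi <- 0
      wmat <- Ncur - A %*% Ncur # refresh against numerical drift
    }

    gcurr <- g[cbind(ei, ej)]
    jumps <- jumps + (gcurr != g_prev)
    g_prev <- gcurr

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      kept <- kept + 1L
      out$r[kept, ] <- r; out$k[kept, ] <- k; out$sigma[kept, ] <- sig
      out$alpha[kept, ] <- alpha[cbind(ei, ej)]
      out$g[kept, ] <- gcurr
      out$Pi[kept, ] <- Pi
    }
  }
  out$jumps <- jumps
  out
}

# Split-R-hat and effective sample size over r, k, sigma draws.
lv_diagnostics <- function(chains, S, E) {
  scalar_mats <- function(name) lapply(chains, `[[`, name)
  params <- c("r", "k", "sigma")
  rhats <- unlist(lapply(params, function(nm) {
    mats <- scalar_mats(nm)
    vapply(seq_len(ncol(mats[[1]])), function(p)
      split_rhat(lapply(mats, function(m) m[, p])), 0)
  }))
  ess <- unlist(lapply(params, function(nm) {
    mats <- scalar_mats(nm)
    vapply(seq_len(ncol(mats[[1]])), function(p)
      sum(vapply(mats, function(m) as.numeric(coda::effectiveSize(m[, p])), 0)), 0)
  }))
  max_rhat <- suppressWarnings(max(rhats, na.rm = TRUE))
  list(rhat = rhats, ess = ess, max_rhat = max_rhat,
       rhat_warn = is.finite(max_rhat) && max_rhat > 1.1)
}

# Gelman-Rubin statistic on split half-chains; NA when degenerate.
split_rhat <- function(draws) {
  halves <- unlist(lapply(draws, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  if (nn < 4) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 1e-12) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
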