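# Hierarchical (group) inference: Bayesian model reduction of Gaussian
# posteriors, parametric empirical Bayes over subjects, automatic pruning
# with Bayesian model averaging, and random-effects Bayesian model selection
# with protected exceedance probabilities.

#' Bayesian model reduction
#'
#' Given a Gaussian prior, the corresponding posterior and a reduced prior
#' over the same parameters, returns in closed form the posterior and the
#' change in log evidence that would have been obtained by inverting the
#' model under the reduced prior — no refitting.
#'
#' @param post_mean,post_cov posterior under the full prior
#' @param prior_mean,prior_cov full prior
#' @param red_mean,red_cov reduced prior
#' @return list with `mean`, `cov`, `dF` (reduced-minus-full log evidence)
#' @export
bayesian_model_reduction <- function(post_mean, post_cov, prior_mean,
                                     prior_cov, red_mean, red_cov) {
  as_cov <- function(x, p) if (is.matrix(x)) x else diag(x, p)
  p <- length(post_mean)
  S  <- as_cov(post_cov, p);  S0 <- as_cov(prior_cov, p)
  R0 <- as_cov(red_cov, p)
  P  <- solve(S); P0 <- solve(S0); Q0 <- solve(R0)
  Pr <- P + Q0 - P0
  ev <- eigen((Pr + t(Pr)) / 2, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("reduced-posterior precision is not positive definite; ",
         "raise the reduced prior variance floor")
  mu  <- as.numeric(post_mean); mu0 <- as.numeric(prior_mean)
  nu0 <- as.numeric(red_mean)
  br <- P %*% mu + Q0 %*% nu0 - P0 %*% mu0
  mur <- solve(Pr, br)
  dF <- 0.5 * (.logdet(P) + .logdet(Q0) - .logdet(P0) - .logdet(Pr)) -
    0.5 * (drop(t(mu) %*% P %*% mu) + drop(t(nu0) %*% Q0 %*% nu0) -
           drop(t(mu0) %*% P0 %*% mu0) - drop(t(mur) %*% Pr %*% mur))
  Sr <- solve(Pr)
  list(mean = setNames(drop(mur), names(post_mean)),
       cov = (Sr + t(Sr)) / 2, dF = dF)
}

#' Group design matrix for the three-group cohort
#'
#' First column is the constant (group mean). Two contrast schemes appear in
#' the analyses: `"groups"` codes PScz>Con and Rel>Con; `"risk"` codes
#' genetic risk (PScz + Rel > Con) and diagnosis (PScz > Rel). Covariates
#' are mean-centered; contrast columns are centered +/- codes.
#'
#' @param group factor/character vector with levels among Con, PScz, Rel
#' @param scheme `"groups"` or `"risk"`
#' @param covariates optional data.frame of numeric covariates
#' @return design matrix (subjects x regressors) with named columns
#' @export
make_design <- function(group, scheme = c("groups", "risk"),
                        covariates = NULL) {
  scheme <- match.arg(scheme)
  group <- as.character(group)
  n <- length(group)
  X <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
  if (scheme == "groups") {
    if (any(group == "PScz"))
      X <- cbind(X, "PScz>Con" = (group == "PScz") - mean(group == "PScz"))
    if (any(group == "Rel"))
      X <- cbind(X, "Rel>Con" = (group == "Rel") - mean(group == "Rel"))
  } else {
    # coded so each regression weight equals the named group difference
    risk <- as.numeric(group %in% c("PScz", "Rel"))
    diagn <- ((group == "PScz") - (group == "Rel")) / 2
    if (var(risk) > 0) X <- cbind(X, "risk" = risk - mean(risk))
    if (var(diagn) > 0) X <- cbind(X, "diagnosis" = diagn - mean(diagn))
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    cv <- sweep(cv, 2, colMeans(cv))
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; check columns: ",
         paste(colnames(X), collapse = ", "))
  }
  X
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Random-effects linear model on first-level Gaussian posteriors: subject
#' parameters are second-level effects (`X beta`) plus Gaussian
#' between-subject variability with a single precision-scaling
#' hyperparameter (diagonal per parameter). The hyperparameter is estimated
#' by maximizing the (closed-form) marginal free energy; effect posterior
#' probabilities come from Bayesian model reduction switching each effect
#' off.
#'
#' @param subject_fits list of fits (each with `mean` and `cov`) over a
#'   shared parameter space
#' @param X design matrix (subjects x regressors), first column the constant
#' @param parameter_selection names of parameters to take to the second
#'   level (default: all shared)
#' @param beta_var second-level prior variance per effect
#' @param between_var base between-subject variance per parameter (scaled by
#'   the estimated hyperparameter); default: the first-level prior variance
#'   divided by 16 when available, else 1/16
#' @param lambda_range search interval for the log precision-scaling
#' @return object of class `peb_fit`: `beta` (matrix parameters x
#'   regressors), `beta_cov`, `prob` (posterior probability each effect is
#'   nonzero), `F`, `lambda`, plus bookkeeping
#' @export
peb_fit <- function(subject_fits, X, parameter_selection = NULL,
                    beta_var = 1 / 16, between_var = NULL,
                    lambda_range = c(-8, 8)) {
  N <- length(subject_fits)
  stopifnot(N >= 1, nrow(X) == N)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; check columns: ",
         paste(colnames(X), collapse = ", "))
  nm <- names(subject_fits[[1]]$mean)
  if (is.null(parameter_selection)) parameter_selection <- nm
  sel <- match(parameter_selection, nm)
  if (anyNA(sel)) stop("parameters not present in subject fits: ",
                       paste(parameter_selection[is.na(sel)], collapse = ", "))
  p <- length(sel); R <- ncol(X)
  if (is.null(between_var)) {
    pv <- subject_fits[[1]]$prior_var
    between_var <- if (!is.null(pv)) unname(pv[sel]) / 16 else rep(1 / 16, p)
  }
  between_var <- rep(between_var, length.out = p)

  # convert each subject's posterior to likelihood form by removing the
  # first-level prior (the second level supplies its own prior on theta_i);
  # without this step group effects inherit the first-level shrinkage
  m <- vector("list", N); S <- vector("list", N)
  for (i in seq_len(N)) {
    f <- subject_fits[[i]]
    cv <- f$cov
    if (is.null(dim(cv))) cv <- diag(cv, length(f$mean))
    Si <- cv[sel, sel, drop = FALSE]
    mi <- as.numeric(f$mean[sel])
    if (!is.null(f$prior_var)) {
      mu0 <- if (!is.null(f$prior_mean)) as.numeric(f$prior_mean[sel])
             else rep(0, p)
      P0i <- diag(1 / as.numeric(f$prior_var[sel]), p)
      Pi_post <- solve(Si)
      Pl <- Pi_post - P0i
      eg <- eigen((Pl + t(Pl)) / 2, symmetric = TRUE)
      # floor: a parameter the data do not inform gets a huge (not
      # negative) likelihood variance
      vals <- pmax(eg$values, max(eg$values, 1) * 1e-8)
      Pl <- eg$vectors %*% diag(vals, p) %*% t(eg$vectors)
      Vl <- solve(Pl)
      mi <- drop(Vl %*% (Pi_post %*% mi - P0i %*% mu0))
      Si <- (Vl + t(Vl)) / 2
    }
    m[[i]] <- mi; S[[i]] <- Si
  }

  nb <- p * R
  Sb0 <- diag(rep(beta_var, nb), nb)
  # marginal free energy given log precision-scaling lambda
  peb_F <- function(lam, want_post = FALSE) {
    Vb <- diag(exp(-lam) * between_var, p)
    Pb_acc <- solve(Sb0)
    gb_acc <- numeric(nb)
    llik <- 0
    for (i in seq_len(N)) {
      Vi <- S[[i]] + Vb
      Wi <- solve(Vi)
      Xi <- kronecker(matrix(X[i, ], 1, R), diag(p))  # p x (p R)
      llik <- llik - 0.5 * .logdet(Vi) - 0.5 * p * log(2 * pi)
      Pb_acc <- Pb_acc + t(Xi) %*% Wi %*% Xi
      gb_acc <- gb_acc + drop(t(Xi) %*% Wi %*% m[[i]])
    }
    mb <- solve(Pb_acc, gb_acc)
    # complete the square: sum_i -0.5 m' W m + 0.5 mb' Pb mb  - 0.5 logdets
    quad <- 0
    for (i in seq_len(N)) {
      Wi <- solve(S[[i]] + Vb)
      quad <- quad - 0.5 * drop(t(m[[i]]) %*% Wi %*% m[[i]])
    }
    Fv <- llik + quad + 0.5 * drop(t(mb) %*% Pb_acc %*% mb) -
      0.5 * .logdet(Sb0) - 0.5 * .logdet(Pb_acc) -
      0.5 * lam^2 / 4   # hyperprior N(0, 4) on the log scaling
    if (!want_post) return(Fv)
    Sbp <- solve(Pb_acc)
    list(F = Fv, mb = mb, Sb = (Sbp + t(Sbp)) / 2, Pb = Pb_acc)
  }
  opt <- optimize(peb_F, lambda_range, maximum = TRUE, tol = 1e-3)
  lam <- opt$maximum
  post <- peb_F(lam, want_post = TRUE)

  beta <- matrix(post$mb, p, R,
                 dimnames = list(parameter_selection, colnames(X)))
  # effect probabilities by BMR: pin each (parameter x regressor) element
  prob <- matrix(NA_real_, p, R, dimnames = dimnames(beta))
  pri_mean <- rep(0, nb); pri_cov <- Sb0
  for (j in seq_len(nb)) {
    red_cov <- Sb0
    red_cov[j, j] <- 1e-8
    r <- bayesian_model_reduction(post$mb, post$Sb, pri_mean, pri_cov,
                                  pri_mean, red_cov)
    prob[j] <- 1 / (1 + exp(r$dF))
  }
  structure(list(beta = beta, beta_cov = post$Sb, prob = prob, F = post$F,
                 lambda = lam, parameters = parameter_selection,
                 regressors = colnames(X), X = X, beta_var = beta_var,
                 between_var = between_var),
            class = "peb_fit")
}

#' Joint posterior probability of a set of second-level effects
#'
#' Probability (by Bayesian model reduction) that the named effects are
#' jointly nonzero: the free-energy softmax of the model with the effects
#' against the model with all of them switched off. For a bilateral
#' hypothesis (the same parameter in both hemispheres) this is the
#' appropriate single test.
#'
#' @param peb a [peb_fit()]
#' @param parameters parameter names (rows of `peb$beta`)
#' @param regressor regressor name (column of `peb$beta`)
#' @return scalar probability
#' @export
peb_joint_prob <- function(peb, parameters, regressor) {
  nb <- length(peb$beta)
  Sb0 <- diag(rep(peb$beta_var, nb), nb)
  idx <- which(rownames(peb$beta) %in% parameters) +
    (match(regressor, colnames(peb$beta)) - 1L) * nrow(peb$beta)
  red <- Sb0
  diag(red)[idx] <- 1e-8
  r <- bayesian_model_reduction(as.numeric(peb$beta), peb$beta_cov,
                                rep(0, nb), Sb0, rep(0, nb), red)
  1 / (1 + exp(r$dF))
}

#' Greedy pruning of second-level effects with Bayesian model averaging
#'
#' Iteratively switches off (pins to zero) the effect whose removal most
#' increases the second-level free energy, until no removal helps; returns
#' the Bayesian model average over all models visited (softmax-weighted,
#' moment-matched).
#'
#' @param peb a [peb_fit()]
#' @return list with `bma_mean`, `bma_sd`, `kept` (logical matrix), `trace`
#' @export
peb_prune <- function(peb) {
  nb <- length(peb$beta)
  Sb0 <- diag(rep(peb$beta_var, nb), nb)
  pri_mean <- rep(0, nb)
  active <- rep(TRUE, nb)
  cur <- list(mean = as.numeric(peb$beta), cov = peb$beta_cov, dF = 0)
  visited <- list(list(w = 0, mean = cur$mean, cov = cur$cov))
  trace <- character()
  red_of <- function(active) {
    rc <- Sb0
    if (any(!active)) diag(rc)[!active] <- 1e-8
    rc
  }
  repeat {
    cand <- which(active)
    best <- NULL
    for (j in cand) {
      a2 <- active; a2[j] <- FALSE
      r <- tryCatch(bayesian_model_reduction(
        as.numeric(peb$beta), peb$beta_cov, pri_mean, Sb0,
        pri_mean, red_of(a2)), error = function(e) NULL)
      if (is.null(r)) next
      visited[[length(visited) + 1]] <- list(w = r$dF, mean = r$mean,
                                             cov = r$cov)
      if (is.null(best) || r$dF > best$dF) best <- c(r, list(j = j, a = a2))
    }
    if (is.null(best) || best$dF <= cur$dF) break
    active <- best$a
    cur <- list(mean = best$mean, cov = best$cov, dF = best$dF)
    trace <- c(trace, sprintf("pruned %d (dF %.2f)", best$j, best$dF))
  }
  w <- vapply(visited, function(v) v$w, numeric(1))
  w <- exp(w - max(w)); w <- w / sum(w)
  mu <- Reduce(`+`, Map(function(v, wi) wi * v$mean, visited, w))
  m2 <- Reduce(`+`, Map(function(v, wi)
    wi * (diag(as.matrix(v$cov)) + v$mean^2), visited, w))
  list(bma_mean = matrix(mu, nrow(peb$beta), ncol(peb$beta),
                         dimnames = dimnames(peb$beta)),
       bma_sd = matrix(sqrt(pmax(m2 - mu^2, 0)), nrow(peb$beta),
                       ncol(peb$beta), dimnames = dimnames(peb$beta)),
       kept = matrix(active, nrow(peb$beta), ncol(peb$beta),
                     dimnames = dimnames(peb$beta)),
       trace = trace)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet-multinomial estimation of model frequencies in the
#' population from per-subject log evidences; exceedance probabilities by
#' seeded Monte Carlo over the Dirichlet posterior; protected exceedance
#' probabilities blend with chance through the Bayesian omnibus risk (the
#' posterior probability that all models are equally frequent).
#'
#' @param log_evidence subjects x models matrix of log evidences (free
#'   energies); needs >= 2 models
#' @param samples Monte Carlo draws for the exceedance probabilities
#' @param seed RNG seed for the draws
#' @param alpha0 Dirichlet prior count per model
#' @return object of class `bms_result`: `expected_p`, `alpha`, `xp`, `pxp`,
#'   `bor`, `assignments`
#' @export
bms_random_effects <- function(log_evidence, samples = 1e5, seed = 1,
                               alpha0 = 1) {
  L <- as.matrix(log_evidence)
  if (!all(is.finite(L))) stop("log evidences must be finite")
  N <- nrow(L); K <- ncol(L)
  if (K < 2) stop("random-effects model selection needs at least 2 models")
  a <- rep(alpha0, K)
  u <- matrix(0, N, K)
  for (it in 1:200) {
    lw <- sweep(L, 2, digamma(a) - digamma(sum(a)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw) / rowSums(exp(lw))
    a_new <- alpha0 + colSums(u)
    if (max(abs(a_new - a)) < 1e-8) { a <- a_new; break }
    a <- a_new
  }
  # exceedance probabilities by Dirichlet Monte Carlo
  xp <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    g <- matrix(rgamma(samples * K, shape = rep(a, each = samples)), samples, K)
    tabulate(max.col(g), K) / samples
  })
  # free energy of the RFX model vs the null (all frequencies equal)
  F1 <- local({
    lw <- sweep(L, 2, digamma(a) - digamma(sum(a)), "+")
    elog <- digamma(a) - digamma(sum(a))
    lgB <- function(al) sum(lgamma(al)) - lgamma(sum(al))
    sum(u * (L + matrix(elog, N, K, byrow = TRUE))) - sum(u * log(pmax(u, 1e-300))) +
      lgB(a) - lgB(rep(alpha0, K)) - sum((a - alpha0) * elog)
  })
  F0 <- sum(apply(L, 1, function(l) {
    mx <- max(l); mx + log(mean(exp(l - mx)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- xp * (1 - bor) + bor / K
  nm <- colnames(L)
  ep <- setNames(a / sum(a), nm)
  structure(list(expected_p = ep, alpha = setNames(a, nm),
                 xp = setNames(xp, nm), pxp = setNames(pxp, nm),
                 bor = bor, assignments = u, models = nm),
            class = "bms_result")
}
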