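# Prior specifications. A prior_spec is a table of named parameters (prior
# mean and variance on the log-scale; variance 0 means fixed) plus a map from
# each name to the parameter paths it controls (with weights), which is how
# parameters are tied across areas or routed into condition (B) effects and
# forward-model settings ("input:*").

#' Construct a prior specification
#'
#' @param table data.frame with columns `name`, `mean`, `var` (log-scale;
#'   `var = 0` marks a fixed parameter).
#' @param map named list: for each `name`, a character vector of parameter
#'   paths (weight 1) or a named numeric vector of path weights.
#' @return object of class `prior_spec`
#' @export
prior_spec <- function(table, map) {
  stopifnot(all(c("name", "mean", "var") %in% names(table)),
            all(table$var >= 0), !anyDuplicated(table$name),
            all(table$name %in% names(map)))
  map <- lapply(map, function(m) {
    if (is.character(m)) setNames(rep(1, length(m)), m) else m
  })
  structure(list(table = as.data.frame(table), map = map), class = "prior_spec")
}

#' Names of free (non-fixed) parameters of a prior specification
#' @param priors a [prior_spec()]
#' @export
free_names <- function(priors) priors$table$name[priors$table$var > 0]

#' @rdname free_names
#' @export
free_mean <- function(priors) {
  t <- priors$table[priors$table$var > 0, ]
  setNames(t$mean, t$name)
}

#' @rdname free_names
#' @export
free_var <- function(priors) {
  t <- priors$table[priors$table$var > 0, ]
  setNames(t$var, t$name)
}

#' Expand named parameter values into path deltas through the prior map
#' @param priors a [prior_spec()]
#' @param theta named numeric over (a subset of) prior names
#' @return named numeric of path deltas
#' @export
expand_theta <- function(priors, theta) {
  out <- numeric()
  for (nm in names(theta)) {
    m <- priors$map[[nm]]
    if (is.null(m)) stop("parameter not in prior map: ", nm)
    for (p in names(m)) out[p] <- (if (is.na(out[p])) 0 else out[p]) +
        m[[p]] * theta[[nm]]
  }
  out[is.na(out)] <- 0
  out
}

.row <- function(name, mean = 0, var = 0)
  data.frame(name = name, mean = mean, var = var, stringsAsFactors = FALSE)

# groups covering every parameter of a network once, all fixed by default
.base_groups <- function(net) {
  k <- .cmc
  tab <- list(); map <- list()
  add <- function(name, paths, mean = 0, var = 0) {
    tab[[length(tab) + 1]] <<- .row(name, mean, var)
    map[[name]] <<- paths
  }
  for (g in k$G$name) add(paste0("G:", g), paste0(net$areas, ":G:", g))
  for (p in k$pops) add(paste0("T:", p), paste0(net$areas, ":T:", p))
  add("S", paste0(net$areas, ":S"))
  for (p in k$pops) add(paste0("J:", p), paste0(net$areas, ":J:", p))
  if (length(net$A_fwd)) add("A:fwd", paste0("A:fwd:", names(net$A_fwd)))
  if (length(net$A_bwd)) add("A:bwd", paste0("A:bwd:", names(net$A_bwd)))
  if (length(net$C)) add("C", paste0("C:", names(net$C)))
  add("D:intrinsic", "D:intrinsic")
  add("D:extrinsic", "D:extrinsic")
  list(tab = tab, map = map)
}

.mmn_model_ids <- c("6G", "4Ga", "4Gb", "4Gc", "4Gd", "6G,D,T")
.assr_model_ids <- c("full", "-J(1)", "-S", "-T", "-w")
.rest_model_ids <- c("baseline")

#' Default priors for a paradigm and model-space member
#'
#' The mismatch-negativity model space frees combinations of the six
#' pyramidal/interneuron connectivity parameters (sp<->ii, dp<->ii, sp and ii
#' self-inhibition; sp self-inhibition per area, the rest tied across areas)
#' together with their deviant-condition modulations; `"6G,D,T"` additionally
#' frees delays and time constants. The ASSR space starts from a full model
#' with empirical priors on the spiny-stellate lead-field contribution J(ss),
#' sigmoid gain S, time constants T and the 4-Hz input bump width w, and the
#' reduced models revert each to its standard (fixed or narrow) prior;
#' `"-w"` sets the width prior to 1 Hz instead of 4 Hz.
#'
#' @param paradigm one of `"rest"`, `"mmn"`, `"assr"`
#' @param model_id model-space label (see Details); defaults to the full
#'   model of the paradigm
#' @param net optionally, the network the priors should cover (defaults to
#'   the paradigm's standard network)
#' @return a [prior_spec()]
#' @export
default_priors <- function(paradigm = c("rest", "mmn", "assr"),
                           model_id = NULL, net = NULL) {
  paradigm <- match.arg(paradigm)
  k <- .cmc
  valid <- switch(paradigm, rest = .rest_model_ids, mmn = .mmn_model_ids,
                  assr = .assr_model_ids)
  if (is.null(model_id)) model_id <- valid[[1]]
  if (!model_id %in% valid)
    stop("unknown model_id '", model_id, "' for paradigm '", paradigm,
         "'; valid: ", paste(valid, collapse = ", "))
  if (is.null(net)) net <- switch(paradigm, rest = single_column_network(),
                                  mmn = mmn_network(), assr = assr_network())
  bg <- .base_groups(net)
  tab <- bg$tab; map <- bg$map
  upd <- function(name, paths, mean = 0, var = 0) {
    hit <- which(vapply(tab, function(r) r$name == name, logical(1)))
    if (length(hit)) tab[[hit]] <<- .row(name, mean, var)
    else tab[[length(tab) + 1]] <<- .row(name, mean, var)
    map[[name]] <<- paths
  }
  drop_grp <- function(name) {
    hit <- which(vapply(tab, function(r) r$name == name, logical(1)))
    if (length(hit)) { tab[[hit]] <<- NULL; map[[name]] <<- NULL }
  }

  if (paradigm == "rest") {
    for (g in k$G$name)
      upd(paste0("G:", g), paste0(net$areas, ":G:", g), 0, k$var_G)
    upd("input:amp", "input:amp", 0, k$var_input)
  }

  if (paradigm == "mmn") {
    six <- c("sp_ii", "ii_sp", "dp_ii", "ii_dp", "ii_ii", "sp_sp")
    setfree <- switch(model_id,
      "6G" = six, "6G,D,T" = six,
      "4Ga" = c("sp_ii", "ii_sp", "sp_sp", "ii_ii"),
      "4Gb" = c("dp_ii", "ii_dp", "sp_sp", "ii_ii"),
      "4Gc" = c("sp_ii", "ii_sp", "dp_ii", "ii_dp"),
      "4Gd" = c("sp_ii", "dp_ii", "sp_sp", "ii_ii"))
    for (g in setfree) {
      if (g == "sp_sp") {
        drop_grp("G:sp_sp")
        for (a in net$areas) {
          upd(paste0("G:sp_sp:", a), paste0(a, ":G:sp_sp"), 0, k$var_G)
          upd(paste0("B:G:sp_sp:", a), paste0("B:deviant:", a, ":G:sp_sp"),
              0, k$var_G)
        }
      } else {
        upd(paste0("G:", g), paste0(net$areas, ":G:", g), 0, k$var_G)
        upd(paste0("B:G:", g), paste0("B:deviant:", net$areas, ":G:", g),
            0, k$var_G)
      }
    }
    if (model_id == "6G,D,T") {
      upd("D:intrinsic", "D:intrinsic", 0, k$var_D)
      upd("D:extrinsic", "D:extrinsic", 0, k$var_D)
      for (p in k$pops) upd(paste0("T:", p), paste0(net$areas, ":T:", p),
                            0, k$var_T)
    }
  }

  if (paradigm == "assr") {
    drop_grp("G:sp_sp")
    for (a in net$areas)
      upd(paste0("G:sp_sp:", a), paste0(a, ":G:sp_sp"), 0, k$var_G)
    upd("G:sp_ii", paste0(net$areas, ":G:sp_ii"), 0, k$var_G)
    upd("G:ii_sp", paste0(net$areas, ":G:ii_sp"), 0, k$var_G)
    upd("D:intrinsic", "D:intrinsic", 0, k$var_D)
    upd("input:amp", "input:amp", 0, k$var_input)
    # empirical priors of the full model; the reduced models revert each
    # parameter's prior mean to its standard value (0 = the resting
    # operating point), staying free at the same variance
    emp <- k$assr_empirical
    upd("J:ss", paste0(net$areas, ":J:ss"),
        if (model_id == "-J(1)") 0 else emp[["J:ss"]], k$var_J)
    upd("S", paste0(net$areas, ":S"),
        if (model_id == "-S") 0 else emp[["S"]], k$var_S)
    for (p in k$pops) {
      m <- if (model_id == "-T") 0 else {
        e <- emp[paste0("T:", p)]; if (is.na(e)) 0 else unname(e)
      }
      upd(paste0("T:", p), paste0(net$areas, ":T:", p), m, k$var_T)
    }
    wmean <- if (model_id == "-w") -log(4) else 0   # 1 Hz vs 4 Hz
    upd("input:width", "input:width", wmean, k$var_input)
  }

  prior_spec(do.call(rbind, tab), map)
}

#' Model-space labels per paradigm
#' @param paradigm one of `"rest"`, `"mmn"`, `"assr"`
#' @export
model_space <- function(paradigm = c("rest", "mmn", "assr")) {
  switch(match.arg(paradigm), rest = .rest_model_ids, mmn = .mmn_model_ids,
         assr = .assr_model_ids)
}

#' Write / read a prior specification as a declarative config file
#'
#' One JSON object per parameter: `{mean, variance, fixed, paths, weights}`.
#' Numeric values are serialized with 17 significant digits so the round trip
#' is bit-exact.
#'
#' @param priors a [prior_spec()]
#' @param path file path
#' @export
write_priors <- function(priors, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- vapply(seq_len(nrow(priors$table)), function(i) {
    nm <- priors$table$name[[i]]
    m <- priors$map[[nm]]
    sprintf(
      '  "%s": {"mean": %s, "variance": %s, "fixed": %s, "paths": [%s], "weights": [%s]}',
      nm, num(priors$table$mean[[i]]), num(priors$table$var[[i]]),
      if (priors$table$var[[i]] == 0) "true" else "false",
      paste(sprintf('"%s"', names(m)), collapse = ", "),
      paste(num(unname(m)), collapse = ", "))
  }, character(1))
  writeLines(c("{", paste(lines, collapse = ",\n"), "}"), path)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  obj <- jsonlite::read_json(path)
  tab <- do.call(rbind, lapply(names(obj), function(nm)
    .row(nm, obj[[nm]]$mean, obj[[nm]]$variance)))
  map <- lapply(obj, function(e)
    setNames(as.numeric(unlist(e$weights)), unlist(e$paths)))
  names(map) <- names(obj)
  prior_spec(tab, map)
}
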