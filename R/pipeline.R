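# End-to-end pipeline: model -> genotypes -> payoffs -> Nash -> dynamics /
# landscape, driven by a serializable configuration.

#' Load, validate or save a run configuration
#'
#' A run configuration is a plain list (JSON or YAML on disk) with fields:
#' \code{model} (either \code{path}/\code{format} or \code{fixture} with
#' \code{kind} and \code{params}), \code{genotypes} (list of genotype
#' specs: \code{label}, \code{deleted_genes} or \code{deleted_reactions},
#' \code{leaky}, \code{uptakes}), optional \code{order},
#' \code{death_rate}, \code{viability}, \code{scan} (axis specs for the
#' fixture factories) and \code{dynamics} (\code{x0} or \code{scenario},
#' \code{invasion_fraction}, \code{t_max}).  A run is reproducible from its
#' configuration alone.
#'
#' @param path JSON or YAML file.
#' @return \code{read_run_config}: the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$model)) stop_input("config needs a model section")
  if (!is.null(cfg$model$path) && !file.exists(cfg$model$path)) {
    stop_input("model file not found: %s", cfg$model$path)
  }
  if (is.null(cfg$model$path) && is.null(cfg$model$fixture)) {
    stop_input("model section needs either a path or a fixture spec")
  }
  invisible(cfg)
}

config_model <- function(cfg) {
  if (!is.null(cfg$model$path)) {
    model <- read_model(cfg$model$path,
                        format = if (is.null(cfg$model$format)) "guess"
                                 else cfg$model$format)
    return(list(model = model, genotypes = NULL))
  }
  fx <- cfg$model$fixture
  params <- if (is.null(fx$params)) list() else fx$params
  switch(fx$kind,
    sucrose = {
      f <- do.call(make_sucrose_fixture, params)
      list(model = f$model, genotypes = f$genotypes)
    },
    two_amino_acid = {
      leak <- params[c("leak_A", "leak_B")]
      params$leak_A <- NULL; params$leak_B <- NULL
      f <- do.call(make_two_amino_acid_fixture, params)
      gs <- if (!is.null(leak$leak_A)) f$genotypes(leak$leak_A, leak$leak_B)
            else NULL
      list(model = f$model, genotypes = gs, fixture = f)
    },
    random_viable = {
      list(model = do.call(make_random_viable_fixture, params),
           genotypes = NULL)
    },
    stop_input("unknown fixture kind: %s", fx$kind))
}

config_genotypes <- function(cfg, model, defaults = NULL) {
  if (is.null(cfg$genotypes)) {
    if (is.null(defaults)) stop_input("config defines no genotypes")
    return(defaults)
  }
  lapply(cfg$genotypes, function(sp) {
    leaky <- if (is.null(sp$leaky)) numeric() else unlist(sp$leaky)
    upt <- if (is.null(sp$uptakes)) numeric() else unlist(sp$uptakes)
    if (!is.null(sp$deleted_genes)) {
      from_gene_deletions(model, unlist(sp$deleted_genes), label = sp$label,
                          leaky = leaky, uptakes = upt)
    } else {
      genotype(sp$label,
               deleted_reactions = if (is.null(sp$deleted_reactions))
                 character() else unlist(sp$deleted_reactions),
               leaky = leaky, uptakes = upt)
    }
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes every intermediate artifact to
#' \code{out_dir}: the model (\code{model.json}), the payoff game
#' (\code{payoffs.json}), the Nash set (\code{nash.json}), the replicator
#' trajectory (\code{trajectory.csv}) when a dynamics section is present,
#' and the landscape (\code{landscape.tsv}) when a scan section is present.
#' Outputs are deterministic for a fixed configuration.
#'
#' @param cfg configuration list (see \code{\link{read_run_config}}).
#' @param out_dir output directory, created if missing.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (\code{model},
#'   \code{genotypes}, \code{game}, \code{nash}, and optionally
#'   \code{trajectory}, \code{landscape}).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  death_rate <- if (is.null(cfg$death_rate)) -0.05 else cfg$death_rate
  viability <- if (is.null(cfg$viability)) 1e-6 else cfg$viability
  order <- if (is.null(cfg$order)) 2L else as.integer(cfg$order)

  mdl <- config_model(cfg)
  write_model(mdl$model, file.path(out_dir, "model.json"))
  say("model: %d metabolites, %d reactions",
      length(mdl$model$metabolites), length(mdl$model$reactions))
  out <- list(model = mdl$model)

  if (!is.null(cfg$scan)) {
    fixture <- mdl$fixture
    factory <- switch(cfg$scan$factory,
      sucrose = do.call(sucrose_factory,
                        if (is.null(cfg$scan$factory_params)) list()
                        else cfg$scan$factory_params),
      two_amino_acid = two_amino_acid_factory(fixture),
      stop_input("unknown scan factory: %s", cfg$scan$factory))
    ls <- scan_landscape(factory,
                         axis1 = cfg$scan$axis1, axis2 = cfg$scan$axis2,
                         order = order, death_rate = death_rate,
                         viability = viability)
    write_landscape(ls, file.path(out_dir, "landscape.tsv"))
    say("landscape: %d cells", nrow(ls$cells))
    out$landscape <- ls
    return(invisible(out))
  }

  genotypes <- config_genotypes(cfg, mdl$model, defaults = mdl$genotypes)
  game <- build_payoff_tensor(mdl$model, unname(genotypes), order = order,
                              death_rate = death_rate, viability = viability)
  write_payoffs(game, file.path(out_dir, "payoffs.json"))
  nash <- find_nash_ilp(game)
  jsonlite::write_json(
    list(equilibria = nash$equilibria, payoffs = nash$payoffs,
         n_equilibria = nash$n_equilibria),
    file.path(out_dir, "nash.json"), auto_unbox = TRUE, digits = NA)
  say("nash: %d equilibria among %d profiles", nash$n_equilibria,
      length(nash$indicator))
  out$genotypes <- genotypes; out$game <- game; out$nash <- nash

  if (!is.null(cfg$dynamics)) {
    dyn <- cfg$dynamics
    t_max <- if (is.null(dyn$t_max)) 500 else dyn$t_max
    traj <- if (!is.null(dyn$scenario)) {
      sc <- invasion_scenario(dyn$scenario)
      invade(game, sc$residents, sc$invaders,
             invasion_fraction = if (is.null(dyn$invasion_fraction)) 0.01
                                 else dyn$invasion_fraction,
             t_max = t_max)
    } else {
      integrate_replicator(unlist(dyn$x0), game, t_max = t_max)
    }
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    say("dynamics: %s",
        if (traj$converged) "converged" else "not converged")
    out$trajectory <- traj
  }
  invisible(out)
}
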