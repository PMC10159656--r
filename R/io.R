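# Result serialization and fixture generation.

params_to_list <- function(fit) {
  list(schema_version = "1.0",
       method = fit$method, G = fit$G, K = fit$K,
       seed = fit$seed, converged = fit$converged, n_iter = fit$n_iter,
       loglik_proxy = fit$loglik_proxy,
       pi = fit$params$pi,
       components = lapply(fit$params$components, function(cm)
         list(M = cm$M, Phi = cm$Phi, Omega = cm$Omega)))
}

#' Write a fit result to a directory
#'
#' Writes \code{params.json} (schema-versioned mixture parameters),
#' \code{assignments.csv} (unit, MAP label, per-component
#' responsibilities), \code{criteria.csv}, \code{elbo_trace.csv} and
#' \code{run.log}.
#'
#' @param fit an \code{mvpln_fit}.
#' @param dir output directory (created if needed).
#' @param unit_ids optional unit labels for \code{assignments.csv}.
#' @return Invisibly, the directory path.
#' @seealso [read_fit_params()]
#' @export
write_fit_result <- function(fit, dir, unit_ids = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_validation("cannot create output directory: ", dir)
  N <- nrow(fit$responsibilities)
  if (is.null(unit_ids)) unit_ids <- paste0("unit", seq_len(N))
  jsonlite::write_json(params_to_list(fit), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  resp <- as.data.frame(fit$responsibilities)
  names(resp) <- paste0("z", seq_len(fit$G))
  utils::write.csv(cbind(data.frame(unit_id = unit_ids,
                                    map_label = fit$map_labels), resp),
                   file.path(dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(data.frame(criterion = names(fit$criteria),
                              value = as.numeric(fit$criteria),
                              direction = attr(fit$criteria, "direction")),
                   file.path(dir, "criteria.csv"), row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(fit$elbo_trace),
                              elbo = fit$elbo_trace),
                   file.path(dir, "elbo_trace.csv"), row.names = FALSE)
  writeLines(c(sprintf("method: %s", fit$method),
               sprintf("G: %d", fit$G),
               sprintf("N: %d", N),
               sprintf("seed: %d", fit$seed),
               sprintf("converged: %s after %d iterations",
                       fit$converged, fit$n_iter),
               sprintf("loglik proxy: %.6f", fit$loglik_proxy),
               sprintf("final ELBO trace: %s",
                       paste(utils::tail(signif(fit$elbo_trace, 8), 5),
                             collapse = " "))),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' Reload mixture parameters written by [write_fit_result()]
#'
#' @param path path to a \code{params.json} file.
#' @return A list with \code{pi} and \code{components} (each with validated
#'   \code{M}, SPD \code{Phi} and \code{Omega}), plus the stored metadata.
#' @export
read_fit_params <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  comps <- lapply(seq_len(raw$G), function(g) {
    cm <- raw$components[[g]]
    M <- as.matrix(cm$M); Phi <- as.matrix(cm$Phi); Omega <- as.matrix(cm$Omega)
    if (!is_spd(Phi) || !is_spd(Omega))
      stop_validation("component ", g, ": stored Phi/Omega not SPD")
    list(M = M, Phi = Phi, Omega = Omega)
  })
  pi <- as.numeric(raw$pi)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop_validation("stored mixing proportions invalid")
  list(pi = pi, components = comps, method = raw$method, G = raw$G,
       seed = raw$seed, schema_version = raw$schema_version)
}

#' Materialize the six benchmark designs as on-disk fixtures
#'
#' For each design, writes \code{max(3, round(25 * scale))} replicate
#' datasets at \code{N} scaled by \code{scale}: a long-format TSV of counts
#' plus a JSON sidecar with the true labels, generator parameters and seed.
#' A manifest records every file and seed, so fixtures are regenerable
#' bit-exactly.
#'
#' @param out_dir output directory.
#' @param scale factor in (0, 1] applied to N and the replicate count.
#' @param seed integer base seed.
#' @param designs subset of design names (default all six).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixtures <- function(out_dir, scale = 1, seed = 1,
                          designs = paste0("sim", 1:6)) {
  if (scale <= 0 || scale > 1) stop_validation("scale must be in (0, 1]")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_validation("cannot create output directory: ", out_dir)
  n_rep <- max(3L, as.integer(round(25 * scale)))
  manifest <- list(scale = scale, seed = seed, n_rep = n_rep,
                   datasets = list())
  for (which in designs) {
    design <- build_sim_design(which, seed = seed, scale = scale)
    for (rep in seq_len(n_rep)) {
      rep_seed <- (seed + 7919L * match(which, paste0("sim", 1:6)) +
                     104729L * rep) %% 2147483647L
      dat <- if (design$family == "mvpln")
        simulate_mvpln_mixture(design, seed = rep_seed)
      else simulate_competitor_mixture(design, seed = rep_seed)
      stem <- sprintf("%s_rep%02d", which, rep)
      write_count_tensor(dat$tensor, file.path(out_dir,
                                               paste0(stem, ".tsv")))
      jsonlite::write_json(
        list(design = which, rep = rep, seed = rep_seed,
             design_seed = seed, scale = scale, N = design$N,
             family = design$family, pi = design$pi,
             labels = dat$labels,
             components = design$components),
        file.path(out_dir, paste0(stem, ".json")),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      manifest$datasets[[stem]] <- list(design = which, rep = rep,
                                        seed = rep_seed, N = design$N)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
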