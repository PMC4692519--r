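#' Normalise a subject's volumes for model training or fitting
#'
#' Applies [normalise_volume()] per modality with its native mode
#' (multiplicative / additive / none) and a per-modality target mean.
#'
#' @param vols named list of [image_volume()].
#' @param bbox optional bounding box (see [normalise_volume()]).
#' @param csf_mask optional CSF mask excluded from the mean.
#' @param target_means named numeric vector of target means per modality;
#'   unnamed scalar applies to all (default 100; additive modalities
#'   default to target 0).
#' @return named list of normalised volumes.
#' @export
normalise_subject <- function(vols, bbox = NULL, csf_mask = NULL,
                              target_means = NULL) {
  out <- vols
  for (mn in names(vols)) {
    tgt <- if (!is.null(target_means) && mn %in% names(target_means)) {
      target_means[[mn]]
    } else if (!is.null(target_means) && is.null(names(target_means))) {
      target_means[[1]]
    } else if (vols[[mn]]$normalisation == "additive") 0 else 100
    out[[mn]] <- normalise_volume(vols[[mn]], bbox = bbox,
                                  csf_mask = csf_mask, target_mean = tgt)
  }
  out
}

#' Train the full segmentation model on an unlabelled cohort
#'
#' Extracts intensity profiles along the reference-mesh normals for every
#' training subject, trains the per-vertex intensity mixture models
#' independently (displacement marginalised), takes each subject's
#' most-likely displacement at every vertex and trains the Normal-Wishart
#' shape model from these by conjugate updating.
#'
#' @param vols list over training subjects of named [image_volume()] lists
#'   (already co-registered and normalised).
#' @param mesh reference [triangle_mesh()].
#' @param priors named list per modality of [prior_profile_spec()] lists.
#' @param config a [mist_config()].
#' @param seed integer seed.
#' @param verbose progress messages.
#' @return a `mist_model`: list with `mesh`, `normals`, `config`,
#'   `modalities`, `intensity` (per-vertex models), `shape`
#'   (`shape_posterior`), `train_displacements` (Nt x N, samples).
#' @export
train_mist <- function(vols, mesh, priors, config, seed = 1,
                       verbose = FALSE) {
  normals <- compute_vertex_normals(mesh)
  pset <- extract_profiles(vols, mesh, normals, config)
  ipriors <- intensity_prior_set(priors[pset$modalities], config)
  models <- train_intensity_models(pset, ipriors, config, seed = seed,
                                   verbose = verbose)
  attr(models, "modalities") <- pset$modalities
  N <- nrow(mesh$vertices)
  S <- dim(pset$profiles)[1]
  disp <- matrix(NA_real_, S, N)
  for (i in seq_len(N)) {
    for (s in seq_len(S)) {
      if (!pset$valid[s, i]) next
      Nm <- length(pset$modalities)
      z <- t(array(pset$profiles[s, , i, , drop = FALSE],
                   dim = c(Nm, pset$k_prime)))  # k' x Nm
      disp[s, i] <- displacement_posterior(z, models[[i]], config)$delta_samples
    }
  }
  # subjects with any invalid vertex are dropped from the shape update
  keep <- stats::complete.cases(disp)
  dist <- edge_distances(mesh)
  sprior <- build_shape_prior(dist, config$shape_h, config$shape_w,
                              n0s = config$shape_n0,
                              alphas = config$shape_alpha)
  spost <- update_shape_posterior(sprior, disp[keep, , drop = FALSE])
  structure(list(mesh = mesh, normals = normals, config = config,
                 modalities = pset$modalities, intensity = models,
                 shape = spost,
                 train_displacements = disp[keep, , drop = FALSE],
                 priors = priors),
            class = "mist_model")
}

#' @export
print.mist_model <- function(x, ...) {
  cat("mist_model:", length(x$intensity), "vertices;",
      length(x$modalities), "modalities (",
      paste(x$modalities, collapse = ", "), ");",
      x$shape$n_subjects, "training subjects\n")
  invisible(x)
}

#' Segment a new subject with a trained model
#'
#' @param vols named list of normalised [image_volume()] for the subject.
#' @param model a [train_mist()] model.
#' @param grid [voxel_grid()] or [image_volume()] for the output mask
#'   (default: the first volume's grid).
#' @param modalities optional modality subset (e.g. T1-only fitting).
#' @return a `segmentation_result` (see [fit_displacements()]).
#' @export
fit_mist <- function(vols, model, grid = NULL, modalities = NULL) {
  if (is.null(grid)) grid <- grid_of(vols[[1]])
  table <- build_likelihood_table(vols, model$mesh, model$normals,
                                  model$intensity, model$config,
                                  modalities = modalities)
  fit_displacements(table, model$shape, model$config, mesh = model$mesh,
                    grid = grid, normals = model$normals)
}

#' Save / load a trained model
#'
#' The model archive is an RDS file; `save_mist_model` additionally writes
#' a human-readable JSON header with the configuration and provenance next
#' to it (`<path>.json`).
#'
#' @param model a `mist_model`.
#' @param path output path (e.g. `model.mist`).
#' @return `path`, invisibly.
#' @export
save_mist_model <- function(model, path) {
  saveRDS(model, path)
  hdr <- list(package = "mist",
              modalities = model$modalities,
              n_vertices = length(model$intensity),
              n_training_subjects = model$shape$n_subjects,
              config = unclass(model$config))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_mist_model
#' @export
read_mist_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mist_model")) stop("not a mist model archive")
  model
}
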