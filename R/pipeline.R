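with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

# Render one fluorophore model into processed 50x50x3 images.
model_to_images <- function(fluors, optics, noise, seed, augment = TRUE,
                            source_id = NULL) {
  stack <- render_stack(fluors, optics)
  stack <- add_noise(stack, noise, seed = seed)
  imgs <- process_stack(stack, size = optics$image_size,
                        source_id = source_id)
  if (!augment) imgs <- imgs[1L]
  imgs
}

images_to_array <- function(imgs) {
  d <- dim(imgs[[1L]])
  out <- array(0L, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

class_labels <- function(classes) {
  if (!is.null(names(classes)) && all(nzchar(names(classes))))
    names(classes) else as.character(classes)
}

#' Experiment configuration: kinetochore radial-displacement classes
#'
#' Image classes are inner-kinetochore (Cse4) radial displacements; each
#' class renders noisy 7-plane stacks of full-spindle models (Cse4 green,
#' Spc29 red) at the default spindle geometry, preprocesses them into
#' eight orientations apiece, and trains the CNN on a 56/24/20 split.
#'
#' @param classes named or unnamed numeric vector of radial displacements
#'   in nm (default `c(0, 25, 50, 100)`); names, if given, are the class
#'   labels (so duplicate displacement values can form control classes).
#' @param images_per_class processed images per class (default 400).
#' @param seed master seed.
#' @param augment use all 8 dihedral orientations per stack; if `FALSE`
#'   (default here) every image comes from an independent stack, which
#'   gives the classifier more model diversity per image.
#' @param spindle,spc29,cse4,optics,noise parameter objects; defaults as
#'   the respective constructors.
#' @param tconfig a [train_config()].
#' @param fractions train/validation/test fractions.
#' @return an object of class `experiment_config`.
#' @export
kinet_radial_config <- function(classes = c(0, 25, 50, 100),
                                images_per_class = 400L, seed = 1L,
                                augment = FALSE,
                                spindle = spindle_params(),
                                spc29 = spc29_params(),
                                cse4 = kinetochore_protein_params(),
                                optics = optics_params(),
                                noise = noise_params(),
                                tconfig = train_config(batch_size = 32L),
                                fractions = c(0.56, 0.24, 0.20)) {
  if (length(classes) < 2L) stop("need >= 2 classes")
  if (images_per_class < 10L) stop("need >= 10 images per class")
  structure(list(experiment = "kinet_radial", classes = classes,
                 images_per_class = as.integer(images_per_class),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 spindle = spindle, spc29 = spc29, cse4 = cse4,
                 optics = optics, noise = noise, tconfig = tconfig,
                 fractions = fractions),
            class = "experiment_config")
}

# Simulate the processed-image set for one radial-displacement class.
simulate_kinet_class <- function(config, displacement, seed) {
  per_stack <- if (config$augment) 8L else 1L
  n_stacks <- ceiling(config$images_per_class / per_stack)
  seeds <- derive_seeds(seed, n_stacks)
  cse4 <- config$cse4
  cse4$radial_displacement <- displacement
  imgs <- vector("list", 0L)
  for (s in seq_len(n_stacks)) {
    sub <- derive_seeds(seeds[s], 4L)
    geo <- build_spindle(config$spindle, seed = sub[1L])
    fl <- combine_fluorophores(
      place_kinetochore_protein(geo, cse4, seed = sub[2L]),
      place_spb(geo, config$spc29, seed = sub[3L]))
    imgs <- c(imgs, model_to_images(fl, config$optics, config$noise,
                                    seed = sub[4L],
                                    augment = config$augment,
                                    source_id = sprintf("stack%04d", s)))
  }
  imgs[seq_len(config$images_per_class)]
}

run_cnn_experiment <- function(config, images, labels) {
  seeds <- derive_seeds(config$seed, 3L)
  split <- with_stage("split",
                      split_dataset(labels, config$fractions,
                                    seed = seeds[1L]))
  model <- build_cnn(cnn_config(length(unique(labels))), seed = seeds[2L])
  tconf <- config$tconfig
  tconf$seed <- seeds[3L]
  model <- with_stage("train", train_cnn(model, images, labels, split, tconf))
  cm <- with_stage("evaluate",
                   evaluate_cnn(model, images[, , , split$test, drop = FALSE],
                                labels[split$test]))
  structure(list(
    experiment = config$experiment,
    confusion = cm,
    test_accuracy = attr(cm, "accuracy"),
    validation_accuracy = model$final_validation_accuracy,
    history = model$history,
    per_class_counts = table(labels),
    split_sizes = vapply(split, length, integer(1L)),
    model = model, config = config, seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment '%s' (seed %d)\n", x$experiment, x$seed))
  cat(sprintf("  images: %s\n",
              paste(sprintf("%s=%d", names(x$per_class_counts),
                            x$per_class_counts), collapse = ", ")))
  if (!is.null(x$validation_accuracy))
    cat(sprintf("  validation accuracy: %.4f\n", x$validation_accuracy))
  if (!is.null(x$test_accuracy))
    cat(sprintf("  test accuracy:       %.4f\n", x$test_accuracy))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}

#' Run the kinetochore radial-displacement experiment
#'
#' Per class: spindle/kinetochore model ensembles are rendered into noisy
#' stacks, preprocessed, pooled, split 56/24/20 and used to train and
#' evaluate the CNN.
#'
#' @param config a [kinet_radial_config()].
#' @return an `experiment_report` with the test confusion matrix,
#'   test and validation accuracies, training history and provenance.
#' @export
run_kinet_radial <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "kinet_radial")
  labels_by_class <- class_labels(config$classes)
  class_seeds <- derive_seeds(config$seed + 1L, length(config$classes))
  imgs <- list(); labels <- character()
  for (k in seq_along(config$classes)) {
    ci <- with_stage(paste0("simulate class ", labels_by_class[k]),
                     simulate_kinet_class(config, config$classes[[k]],
                                          class_seeds[k]))
    imgs <- c(imgs, ci)
    labels <- c(labels, rep(labels_by_class[k], length(ci)))
  }
  run_cnn_experiment(config, images_to_array(imgs), labels)
}

#' Experiment configuration: rDNA crosslink-duration classes
#'
#' Image classes are mean crosslink durations of the rDNA polymer model
#' (defaults 0.09, 0.19 and 1.6 s). Snapshots of independent rDNA-only
#' trajectories are rendered as red-channel stacks, preprocessed and
#' classified by the CNN.
#'
#' @param mu_classes named or unnamed numeric vector of mean crosslink
#'   durations (s).
#' @param images_per_class processed images per class (default 300).
#' @param n_trajectories independent trajectories per class; default
#'   (`NULL`) uses one trajectory per ~5 exposures so the per-trajectory
#'   sampling window stays short (1250 steps) at any dataset scale.
#' @param sample_every steps between snapshots (default 250).
#' @param burn_in equilibration steps per trajectory (default 2000).
#' @param polymer_base a [polymer_params()] template whose `mu` is
#'   replaced per class (default [rdna_only_params()]).
#' @inheritParams kinet_radial_config
#' @return an object of class `experiment_config`.
#' @export
nucleolus_mu_config <- function(mu_classes = c(0.09, 0.19, 1.6),
                                images_per_class = 300L, seed = 1L,
                                augment = TRUE, n_trajectories = NULL,
                                sample_every = 250L, exposure_frames = 1L,
                                frame_step = 10L, burn_in = 3000L,
                                polymer_base = rdna_only_params(),
                                optics = optics_params(),
                                noise = noise_params(),
                                tconfig = train_config(batch_size = 16L),
                                fractions = c(0.56, 0.24, 0.20)) {
  if (length(mu_classes) < 2L) stop("need >= 2 classes")
  if (images_per_class < 10L) stop("need >= 10 images per class")
  structure(list(experiment = "nucleolus_mu", classes = mu_classes,
                 images_per_class = as.integer(images_per_class),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 n_trajectories = if (is.null(n_trajectories)) NULL else
                   as.integer(n_trajectories),
                 sample_every = as.integer(sample_every),
                 exposure_frames = as.integer(exposure_frames),
                 frame_step = as.integer(frame_step),
                 burn_in = as.integer(burn_in),
                 polymer_base = polymer_base,
                 optics = optics, noise = noise, tconfig = tconfig,
                 fractions = fractions),
            class = "experiment_config")
}

simulate_mu_class <- function(config, mu, seed) {
  per_stack <- if (config$augment) 8L else 1L
  n_stacks <- ceiling(config$images_per_class / per_stack)
  n_traj <- config$n_trajectories
  if (is.null(n_traj)) n_traj <- max(4L, ceiling(n_stacks / 5L))
  snaps_per_traj <- ceiling(n_stacks / n_traj)
  params <- config$polymer_base
  params$mu <- mu
  nf <- config$exposure_frames
  fs <- config$frame_step
  per_block <- config$sample_every %/% fs
  seeds <- derive_seeds(seed, n_traj + n_stacks)
  imgs <- vector("list", 0L)
  s <- 0L
  for (tj in seq_len(n_traj)) {
    # sample sub-frames densely; each exposure integrates the last
    # `nf` sub-frames of its block
    traj <- run_trajectory(params,
                           total_steps = snaps_per_traj *
                             config$sample_every,
                           sample_every = fs,
                           seed = seeds[tj], burn_in = config$burn_in)
    for (k in seq_len(snaps_per_traj)) {
      s <- s + 1L
      if (s > n_stacks) break
      frame_ix <- (k - 1L) * per_block + (per_block - nf + 1L):per_block
      frames <- lapply(frame_ix, function(fi)
        traj$snapshots[[fi]][traj$rdna_idx, , drop = FALSE])
      ctr <- colMeans(do.call(rbind, frames))
      stack <- NULL
      for (fr in frames) {
        fc <- fr - matrix(ctr, nrow(fr), 3L, byrow = TRUE)
        fl <- fluorophore_set(fc[, 1L], fc[, 2L], fc[, 3L],
                              channel = "red")
        st <- render_stack(fl, config$optics)
        stack <- if (is.null(stack)) unclass(st) else
          unclass(stack) + unclass(st)
      }
      stack <- structure(stack / nf, class = "image_stack",
                         optics = config$optics)
      stack <- add_noise(stack, config$noise, seed = seeds[n_traj + s])
      im <- process_stack(stack, size = config$optics$image_size,
                          source_id = sprintf("mu%g_t%d_s%d", mu, tj, k))
      if (!config$augment) im <- im[1L]
      imgs <- c(imgs, im)
    }
  }
  imgs[seq_len(config$images_per_class)]
}

#' Run the rDNA crosslink-duration experiment
#'
#' @param config a [nucleolus_mu_config()].
#' @return an `experiment_report` (see [run_kinet_radial()]).
#' @export
run_nucleolus_mu <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "nucleolus_mu")
  labels_by_class <- class_labels(config$classes)
  class_seeds <- derive_seeds(config$seed + 2L, length(config$classes))
  imgs <- list(); labels <- character()
  for (k in seq_along(config$classes)) {
    ci <- with_stage(paste0("simulate mu = ", config$classes[[k]]),
                     simulate_mu_class(config, config$classes[[k]],
                                       class_seeds[k]))
    imgs <- c(imgs, ci)
    labels <- c(labels, rep(labels_by_class[k], length(ci)))
  }
  run_cnn_experiment(config, images_to_array(imgs), labels)
}

#' Experiment configuration: feature importance and SVM validation
#'
#' Two simulated image classes — by default inner-kinetochore (Cse4,
#' converged at the MT axis) versus outer-kinetochore (Nuf2, distributed
#' within 50 nm of the plus ends) labelling, both with Spc29-marked SPBs.
#' Features are extracted, ranked by PCA importance, and validated by
#' repeated Gaussian-kernel SVMs on all features, the two most important,
#' and the two least important.
#'
#' @param images_per_class processed images per class (default 200).
#' @param n_reps SVM repetitions per feature subset (default 30).
#' @param inner,outer placement parameter objects for the two classes.
#' @inheritParams kinet_radial_config
#' @return an object of class `experiment_config`.
#' @export
feature_analysis_config <- function(images_per_class = 200L, seed = 1L,
                                    augment = FALSE, n_reps = 30L,
                                    spindle = spindle_params(),
                                    spc29 = spc29_params(),
                                    inner = kinetochore_protein_params(),
                                    outer = nuf2_params(),
                                    optics = optics_params(),
                                    noise = noise_params(),
                                    tconfig = train_config()) {
  structure(list(experiment = "feature_analysis",
                 images_per_class = as.integer(images_per_class),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 n_reps = as.integer(n_reps),
                 spindle = spindle, spc29 = spc29,
                 inner = inner, outer = outer,
                 optics = optics, noise = noise, tconfig = tconfig),
            class = "experiment_config")
}

simulate_protein_class <- function(config, protein, seed, source_prefix) {
  per_stack <- if (config$augment) 8L else 1L
  n_stacks <- ceiling(config$images_per_class / per_stack)
  seeds <- derive_seeds(seed, n_stacks)
  imgs <- vector("list", 0L)
  for (s in seq_len(n_stacks)) {
    sub <- derive_seeds(seeds[s], 4L)
    geo <- build_spindle(config$spindle, seed = sub[1L])
    marker <- if (inherits(protein, "nuf2_params"))
      place_nuf2(geo, protein, seed = sub[2L]) else
        place_kinetochore_protein(geo, protein, seed = sub[2L])
    fl <- combine_fluorophores(marker,
                               place_spb(geo, config$spc29, seed = sub[3L]))
    imgs <- c(imgs, model_to_images(fl, config$optics, config$noise,
                                    seed = sub[4L],
                                    augment = config$augment,
                                    source_id = paste0(source_prefix, s)))
  }
  imgs[seq_len(config$images_per_class)]
}

#' Run the feature-importance analysis
#'
#' Extracts the 13 features from both image classes (flagged images are
#' dropped; the run aborts if more than half are flagged), ranks features
#' by PCA importance, and compares repeated-SVM accuracy distributions for
#' all features, the top two and the bottom two, with Wilcoxon rank-sum
#' p-values.
#'
#' @param config a [feature_analysis_config()].
#' @return an object of class `feature_analysis_report`: the importance
#'   ranking, three `accuracy_distribution`s, the two p-values, and the
#'   feature table used.
#' @export
run_feature_analysis <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$experiment == "feature_analysis")
  seeds <- derive_seeds(config$seed + 3L, 5L)
  inner <- with_stage("simulate inner class",
                      simulate_protein_class(config, config$inner,
                                             seeds[1L], "inner"))
  outer <- with_stage("simulate outer class",
                      simulate_protein_class(config, config$outer,
                                             seeds[2L], "outer"))
  images <- c(inner, outer)
  labels <- rep(c("inner", "outer"), c(length(inner), length(outer)))
  tab <- with_stage("feature extraction", feature_table(images, labels))
  n_flagged <- length(attr(tab, "flagged"))
  if (n_flagged > length(images) / 2)
    stop(sprintf(
      "feature extraction flagged %d of %d images; check foci content",
      n_flagged, length(images)))
  x <- zscore(as.matrix(tab[, feature_names]))
  imp <- pca_importance(x, retain = "kaiser")
  top2 <- imp$ranking$feature[1:2]
  bottom2 <- imp$ranking$feature[(nrow(imp$ranking) - 1L):nrow(imp$ranking)]
  acc_all <- repeated_accuracy(x, tab$class, NULL, config$n_reps,
                               seed = seeds[3L], subset_label = "all")
  acc_top <- repeated_accuracy(x, tab$class, top2, config$n_reps,
                               seed = seeds[4L], subset_label = "top2")
  acc_bottom <- repeated_accuracy(x, tab$class, bottom2, config$n_reps,
                                  seed = seeds[5L], subset_label = "bottom2")
  structure(list(
    importance = imp, top2 = top2, bottom2 = bottom2,
    accuracy = list(all = acc_all, top2 = acc_top, bottom2 = acc_bottom),
    p_top_vs_all = compare_distributions(acc_top, acc_all),
    p_bottom_vs_all = compare_distributions(acc_bottom, acc_all),
    features = tab, n_flagged = n_flagged,
    config = config, seed = config$seed
  ), class = "feature_analysis_report")
}

#' @export
print.feature_analysis_report <- function(x, ...) {
  cat("Feature-importance analysis\n")
  print(x$importance)
  for (a in x$accuracy) print(a)
  cat(sprintf("  top-2 vs all features:    p = %.4g\n", x$p_top_vs_all))
  cat(sprintf("  bottom-2 vs all features: p = %.4g\n", x$p_bottom_vs_all))
  invisible(x)
}

#' Classify external images with a trained CNN
#'
#' Reads 16-bit RGB TIFF images (50x50x3, already preprocessed) from a
#' directory and tabulates the predicted class counts; unreadable or
#' wrongly shaped files are skipped with a message.
#'
#' @param model a trained `kinet_cnn`.
#' @param dir directory of `.tif`/`.tiff` files.
#' @return named integer vector of per-class counts (attribute `skipped`
#'   lists skipped files); counts sum to the number of images read.
#' @export
classify_external <- function(model, dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  imgs <- list(); skipped <- character()
  for (f in files) {
    img <- tryCatch(read_processed_image(f), error = function(e) NULL)
    ok <- !is.null(img) &&
      identical(dim(img)[1:2],
                rep(as.integer(model$config$input_size), 2L))
    if (ok) imgs[[length(imgs) + 1L]] <- img else
      skipped <- c(skipped, basename(f))
  }
  if (length(skipped))
    message("skipped ", length(skipped), " file(s): ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  counts <- setNames(integer(length(model$classes)), model$classes)
  if (length(imgs)) {
    pred <- predict.kinet_cnn(model, images_to_array(imgs))
    tt <- table(pred)
    counts[names(tt)] <- as.integer(tt)
  }
  structure(counts, skipped = skipped)
}
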