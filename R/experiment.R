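#' Experiment arms
#'
#' The study compares eleven arms: the un-augmented baseline (`"0"`) and ten
#' one-to-one augmentation arms. Audio-level arms re-render spectrograms
#' from the augmented audio; image-level arms transform the cached baseline
#' images; the masking arm operates on the Mel matrix before rendering.
#'
#' @return a named character vector mapping arm id to augmentation method.
#' @export
experiment_arms <- function() {
  c(
    "0" = "baseline", "1" = "pitch_time", "2" = "noise",
    "3.1" = "hflip", "3.2" = "vflip",
    "4.1" = "sv", "4.2" = "pca", "4.3" = "color_filter",
    "5" = "mask", "6" = "hflip_pca", "7" = "hflip_sv"
  )
}

#' Experiment configuration
#'
#' Bundles every stage's configuration plus the master seed. All randomness
#' in a run (dataset synthesis, fold assignment, augmentation draws, weight
#' initialisation, shuffling) derives deterministically from `seed`.
#'
#' @param n_normal,n_abnormal synthetic dataset class sizes (defaults
#'   318 and 82: 400 recordings at the study's ~3.9:1 imbalance).
#' @param pcg a [pcg_config()].
#' @param preprocess a [preprocess_config()].
#' @param spectral a [spectrogram_params()].
#' @param model a [model_spec()].
#' @param k folds (default 5).
#' @param arms arm ids to run (see [experiment_arms()]).
#' @param seed master seed.
#' @param data_dir optional directory of existing WAVs with a label
#'   manifest (see [read_wav_directory()]); when given, `n_normal`,
#'   `n_abnormal` and `pcg` are ignored and the recordings are used as-is.
#' @param out_dir working directory for WAVs and reports (default: a
#'   session temporary directory).
#' @return a list of class `pcg_experiment_config`.
#' @export
experiment_config <- function(n_normal = 318L, n_abnormal = 82L,
                              pcg = pcg_config(),
                              preprocess = preprocess_config(),
                              spectral = spectrogram_params(),
                              model = model_spec(),
                              k = 5L,
                              arms = names(experiment_arms()),
                              seed = 1L,
                              data_dir = NULL,
                              out_dir = NULL) {
  bad <- setdiff(arms, names(experiment_arms()))
  if (length(bad)) config_error(paste0("unknown arms: ", paste(bad, collapse = ", ")))
  structure(
    list(
      n_normal = n_normal, n_abnormal = n_abnormal, pcg = pcg,
      preprocess = preprocess, spectral = spectral, model = model,
      k = as.integer(k), arms = arms, seed = as.integer(seed),
      data_dir = data_dir, out_dir = out_dir
    ),
    class = "pcg_experiment_config"
  )
}

#' Load a manifest into an in-memory records table
#'
#' Reads every WAV referenced by the manifest and renders its baseline
#' Mel-spectrogram and colour image once; augmentation arms reuse these
#' cached objects.
#'
#' @param manifest a manifest tibble (`record_id`, `path`, `label`).
#' @param spectral a [spectrogram_params()].
#' @return a tibble with `record_id`, `label` and list-columns `rec`,
#'   `mel`, `img`.
#' @export
load_records <- function(manifest, spectral = spectrogram_params()) {
  rows <- purrr::pmap(
    list(manifest$path, manifest$label, manifest$record_id),
    function(path, label, id) {
      rec <- read_recording(path, label, id)
      mel <- to_mel_db(power_spectrogram(rec, spectral), spectral, rec$sample_rate)
      img <- render_image(mel, spectral)
      tibble(record_id = id, label = as.integer(label),
             rec = list(rec), mel = list(mel), img = list(img))
    }
  )
  bind_rows(rows)
}

#' One-to-one augmentation of a training set
#'
#' For every training record, generates exactly one augmented item with the
#' same label (N items become 2N). Audio-level methods re-render the
#' spectrogram image from the transformed audio; the masking method
#' transforms the Mel matrix and re-renders; image-level methods transform
#' the cached image. Every augmented row records its source record, method
#' and seed (the serialisable augmentation spec). Test records must never
#' be passed to this function.
#'
#' @param train a records table (see [load_records()]); rows are the
#'   training fold only.
#' @param method one of `"pitch_time"`, `"noise"`, `"hflip"`, `"vflip"`,
#'   `"sv"`, `"pca"`, `"color_filter"`, `"mask"`, `"hflip_pca"`
#'   (PCA then horizontal flip), `"hflip_sv"` (SV then horizontal flip).
#' @param master_seed integer seed; per-item seeds derive from it.
#' @param spectral a [spectrogram_params()] for re-rendering.
#' @return a records table of 2N rows; augmented rows have
#'   `source_record_id`, `method` and `aug_seed` set.
#' @export
augment_training_set <- function(train, method, master_seed = 1L,
                                 spectral = spectrogram_params()) {
  methods <- setdiff(unname(experiment_arms()), "baseline")
  if (!method %in% methods) {
    config_error(paste0("unknown augmentation method: ", method))
  }
  if (nrow(train) == 0) config_error("empty training set.")
  aug_rows <- purrr::map(seq_len(nrow(train)), function(i) {
    id <- train$record_id[i]
    seed_i <- derive_seed(master_seed, method, id)
    rec <- train$rec[[i]]
    mel <- train$mel[[i]]
    img <- train$img[[i]]
    if (method %in% c("pitch_time", "noise")) {
      rec2 <- if (method == "pitch_time") {
        pitch_time_augment(rec, seed_i)
      } else {
        inject_awgn(rec, seed_i)
      }
      mel2 <- to_mel_db(power_spectrogram(rec2, spectral), spectral, rec2$sample_rate)
      img2 <- render_image(mel2, spectral)
    } else if (method == "mask") {
      rec2 <- rec
      mel2 <- time_frequency_mask(mel, seed_i)
      img2 <- render_image(mel2, spectral)
    } else {
      rec2 <- rec
      mel2 <- mel
      img2 <- switch(method,
        hflip_pca = compose_method(img, "pca", "hflip", seed_i),
        hflip_sv = compose_method(img, "sv", "hflip", seed_i),
        apply_image_method(img, method, seed_i)
      )
    }
    tibble(
      record_id = paste0(id, "_", gsub("[^a-z0-9]", "", method)),
      label = train$label[i],
      rec = list(rec2), mel = list(mel2), img = list(img2),
      source_record_id = id, method = method, aug_seed = seed_i
    )
  })
  orig <- mutate(train,
                 source_record_id = NA_character_,
                 method = NA_character_, aug_seed = NA_integer_)
  bind_rows(orig, bind_rows(aug_rows))
}

#' Run the full augmentation-comparison experiment
#'
#' Builds (or ingests) the dataset, preprocesses it, creates one stratified
#' fold plan shared by every arm, and for each arm and fold: augments the
#' training fold one-to-one (except the baseline), trains the fixed CNN
#' from a fold-specific weight seed, and scores the untouched test fold.
#' Augmented items whose source sits in the test fold can never enter
#' training (asserted per fold). Returns per-fold metrics, per-arm
#' summaries and fold-paired mean-difference CIs against the baseline arm.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-arm progress (default TRUE).
#' @return an object of class `pcg_experiment`; see [tidy.pcg_experiment()],
#'   [glance.pcg_experiment()], [autoplot.pcg_experiment()] and
#'   [write_report()].
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  out_dir <- cfg$out_dir %||% tempfile("pcgaug_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (is.null(cfg$data_dir)) {
    say("synthesising %d + %d recordings", cfg$n_normal, cfg$n_abnormal)
    manifest <- generate_dataset(cfg$n_normal, cfg$n_abnormal, cfg$pcg,
                                 cfg$seed, file.path(out_dir, "raw"))
  } else {
    manifest <- read_wav_directory(cfg$data_dir)
  }
  manifest <- preprocess_pipeline(manifest, cfg$preprocess,
                                  file.path(out_dir, "preprocessed"))
  if (nrow(manifest) == 0) degenerate_error("no recordings survived preprocessing.")

  say("rendering %d baseline spectrogram images", nrow(manifest))
  records <- load_records(manifest, cfg$spectral)

  folds <- stratified_folds(manifest, cfg$k, derive_seed(cfg$seed, "folds"))
  plan_hash <- attr(folds, "fold_hash")
  records <- left_join(records, select(folds, "record_id", "fold"), by = "record_id")

  arms_map <- experiment_arms()
  spec_hash <- model_spec_hash(cfg$model)
  metrics <- list()
  curves <- list()
  arm_hashes <- character()

  for (arm in cfg$arms) {
    method <- arms_map[[arm]]
    arm_hashes[arm] <- plan_hash  # the single shared plan, by construction
    say("arm %s (%s)", arm, method)
    for (j in seq_len(cfg$k)) {
      test_ids <- records$record_id[records$fold == j]
      train <- filter(records, .data$fold != j)
      if (method != "baseline") {
        train <- augment_training_set(train, method,
                                      derive_seed(cfg$seed, "aug", arm, j),
                                      cfg$spectral)
        leaked <- intersect(train$source_record_id, test_ids)
        if (length(leaked)) {
          abort(paste0("leakage guard tripped: augmented test records in training: ",
                       paste(leaked, collapse = ", ")),
                class = "pcgaug_leakage_error")
        }
        if (nrow(train) != 2 * sum(records$fold != j)) {
          abort("one-to-one augmentation must double the training set.",
                class = "pcgaug_internal_error")
        }
      }
      model <- train_cnn(train$img, train$label, cfg$model,
                         seed = derive_seed(cfg$seed, "weights", j))
      test <- filter(records, .data$fold == j)
      scores <- predict_scores(model, test$img)
      metrics[[length(metrics) + 1L]] <-
        mutate(fold_metrics(scores, test$label),
               arm = arm, method = method, fold = j,
               n_train = nrow(train), n_test = nrow(test),
               final_loss = tail(model$loss_history, 1),
               .before = 1)
      cv <- roc_pr_curves(scores, test$label)
      curves[[length(curves) + 1L]] <- bind_rows(
        mutate(cv$roc, curve = "roc", x = .data$fpr, y = .data$tpr),
        mutate(cv$pr, curve = "pr", x = .data$recall, y = .data$precision)
      ) %>%
        mutate(arm = arm, fold = j) %>%
        select("arm", "fold", "curve", "x", "y", "threshold")
    }
  }
  metrics <- bind_rows(metrics)

  metric_cols <- c("accuracy", "sensitivity", "specificity_at_sens",
                   "roc_auc", "pr_auc", "f1")
  summary <- metrics %>%
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$arm, .data$method, .data$metric) %>%
    summarise(
      mean = mean(.data$value),
      conf.low = mean_ci(.data$value)["lo"],
      conf.high = mean_ci(.data$value)["hi"],
      .groups = "drop"
    )

  comparisons <- NULL
  if ("0" %in% cfg$arms) {
    base <- filter(metrics, .data$arm == "0") %>% arrange(.data$fold)
    comparisons <- bind_rows(lapply(setdiff(cfg$arms, "0"), function(a) {
      am <- filter(metrics, .data$arm == a) %>% arrange(.data$fold)
      bind_rows(lapply(metric_cols, function(mc) {
        mutate(paired_mean_difference_ci(am[[mc]], base[[mc]]),
               arm = a, metric = mc, .before = 1)
      }))
    }))
  }

  structure(
    list(
      config = cfg, manifest = manifest, fold_plan = folds,
      fold_hash = plan_hash, arm_fold_hashes = arm_hashes,
      model_spec_hash = spec_hash,
      metrics = metrics, summary = summary, comparisons = comparisons,
      curves = bind_rows(curves),
      runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "pcg_experiment"
  )
}

#' @export
print.pcg_experiment <- function(x, ...) {
  cat(sprintf("<pcg_experiment> %d arms x %d folds on %d recordings (%.0f s)\n",
              length(unique(x$metrics$arm)), attr(x$fold_plan, "k"),
              nrow(x$manifest), x$runtime_s))
  print(x$summary %>% filter(.data$metric %in% c("roc_auc", "pr_auc")))
  invisible(x)
}
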