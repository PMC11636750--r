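# End-to-end orchestration: phantom generation -> preprocessing -> DBN
# segmentation -> feature extraction -> SOI-GRS selection -> EHHO-tuned
# GOSS-GBDT classification -> evaluation.  Every stage is seeded from the
# pipeline seed, and per-stage toggles support ablation runs.

#' Pipeline configuration
#'
#' @param n_phantoms Number of phantoms to generate.
#' @param phantom Phantom configuration; the default uses 96 x 96 slices to
#'   keep the full benchmark desk-scale.
#' @param prevalence Cancer prevalence of the generated dataset.
#' @param split_fracs Train/validation/test fractions.
#' @param preprocess,segmentation,feature_selection,hyperparam_opt Stage
#'   toggles (classification is always enabled).
#' @param train Segmenter training configuration ([train_config()]).
#' @param spiral Feature-selection configuration ([spiral_config()]).
#' @param gbdt Baseline classifier parameters ([gbdt_params()]).
#' @param tune_hawks,tune_iters EHHO tuning budget.
#' @param segment_train_images Cap on images used to train the segmenter.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_phantoms = 400L,
                            phantom = phantom_config(
                              height = 96, width = 96,
                              tumor_radius_range = c(7, 13),
                              tumor_intensity = 0.40,
                              gaussian_sigma = 0.03, sp_density = 0.02
                            ),
                            prevalence = 0.5,
                            split_fracs = c(0.4, 0.3, 0.3),
                            preprocess = TRUE, segmentation = TRUE,
                            feature_selection = TRUE, hyperparam_opt = TRUE,
                            train = train_config(),
                            spiral = spiral_config(m = 24L, k_max = 60L),
                            gbdt = gbdt_params(nti = 60L),
                            tune_hawks = 5L, tune_iters = 5L,
                            segment_train_images = 60L,
                            seed = 7L) {
  structure(list(
    n_phantoms = as.integer(n_phantoms), phantom = phantom,
    prevalence = prevalence, split_fracs = split_fracs,
    preprocess = preprocess, segmentation = segmentation,
    feature_selection = feature_selection, hyperparam_opt = hyperparam_opt,
    train = train, spiral = spiral, gbdt = gbdt,
    tune_hawks = as.integer(tune_hawks), tune_iters = as.integer(tune_iters),
    segment_train_images = as.integer(segment_train_images),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full lung-CT analysis pipeline on synthetic phantoms
#'
#' Executes generate -> preprocess -> segment -> extract -> select -> tune ->
#' train -> evaluate over stratified train/validation/test splits.  Disabled
#' stages degrade gracefully: without preprocessing the raw noisy images are
#' used; without segmentation features are extracted from the whole image;
#' without feature selection all 50 features reach the classifier; without
#' hyperparameter optimization the baseline GBDT parameters are used.
#' Fully deterministic for a fixed configuration.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `eval_report`: test metrics, ROC points and AUC,
#'   confusion matrix, mean segmentation Dice over cancerous test images,
#'   selected feature names, tuned parameters, and per-stage runtimes.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  timing <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
    timing[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  ds <- clock("generate", generate_dataset(
    cfg$n_phantoms, prevalence = cfg$prevalence,
    split_fracs = cfg$split_fracs, cfg = cfg$phantom,
    seed = derive_seed(cfg$seed, 1L)
  ))
  raw <- lapply(ds$samples, `[[`, "image")
  masks <- lapply(ds$samples, `[[`, "mask")
  labels <- as.integer(ds$labels == "cancer")

  imgs <- clock("preprocess", {
    if (cfg$preprocess) lapply(raw, preprocess_image) else raw
  })

  seg_masks <- clock("segment", {
    if (cfg$segmentation) {
      tr_idx <- ds$split$train
      tr_cancer <- tr_idx[labels[tr_idx] == 1]
      use <- tr_idx[seq_len(min(length(tr_idx), cfg$segment_train_images))]
      if (!any(labels[use] == 1)) use <- c(use, tr_cancer[1])
      tcfg <- cfg$train
      tcfg$seed <- derive_seed(cfg$seed, 2L)
      model <- train_segmenter(imgs[use], masks[use], tcfg)
      lapply(imgs, segment, model = model)
    } else {
      lapply(imgs, function(im) matrix(1L, nrow(im), ncol(im)))
    }
  })

  feats <- clock("extract", feature_table(imgs, seg_masks, labels,
                                          fallback_whole_image = TRUE))

  sel_names <- clock("select", {
    if (cfg$feature_selection) {
      tr <- ds$split$train
      Xd <- discretize_features(feats[tr, setdiff(names(feats), "label")])
      scfg <- cfg$spiral
      scfg$seed <- derive_seed(cfg$seed, 3L)
      bits <- select_features(Xd, feats$label[tr], scfg)
      setdiff(names(feats), "label")[bits]
    } else {
      setdiff(names(feats), "label")
    }
  })

  Xsel <- feats[, sel_names, drop = FALSE]
  y <- feats$label
  tr <- ds$split$train; va <- ds$split$validation; te <- ds$split$test

  params <- clock("tune", {
    if (cfg$hyperparam_opt) {
      tune_gbdt(Xsel[tr, , drop = FALSE], y[tr],
                cv_folds = 3L, n_hawks = cfg$tune_hawks, T = cfg$tune_iters,
                base = cfg$gbdt, seed = derive_seed(cfg$seed, 4L))
    } else {
      cfg$gbdt
    }
  })

  model <- clock("train", {
    p <- params
    p$seed <- derive_seed(cfg$seed, 5L)
    trva <- sort(c(tr, va))
    fit_gbdt(Xsel[trva, , drop = FALSE], y[trva], p)
  })

  report <- clock("evaluate", {
    scores <- predict_proba(model, Xsel[te, , drop = FALSE])
    pred <- as.integer(scores >= 0.5)
    cm <- confusion_matrix(pred = pred, truth = y[te])
    metrics <- compute_metrics(cm)
    roc <- roc_curve(scores, y[te])
    cancer_te <- te[y[te] == 1]
    dice <- if (length(cancer_te)) {
      dice_coefficient(seg_masks[cancer_te], masks[cancer_te])
    } else NA_real_
    list(metrics = metrics, confusion = cm, roc = roc, dice = dice,
         scores = scores, pred = pred, truth = y[te])
  })

  structure(c(report, list(
    selected_features = sel_names,
    params = params[c("mdl", "nti", "nl", "md")],
    n = cfg$n_phantoms, seed = cfg$seed, runtime = timing
  )), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  acc <- x$metrics$value[x$metrics$metric == "accuracy"]
  cat(sprintf("<eval_report> n=%d seed=%d | test accuracy %.4f, AUC %.4f, mean Dice %.4f\n",
              x$n, x$seed, acc, x$roc$auc, x$dice))
  cat(sprintf("  selected features: %d | GBDT mdl=%d nti=%d nl=%d md=%d\n",
              length(x$selected_features), x$params$mdl, x$params$nti,
              x$params$nl, x$params$md))
  invisible(x)
}

#' Tidy metric summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble of metrics including AUC and mean Dice.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::add_row(x$metrics,
                  metric = c("auc", "dice"),
                  value = c(x$roc$auc, x$dice))
}

#' ROC plot for an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @export
autoplot.eval_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot", call. = FALSE)
  }
  ggplot2::ggplot(object$roc$points, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$roc$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
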