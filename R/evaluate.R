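# Evaluation: Dice similarity coefficient and the train/test-domain
# experiment grid run on phantom data.

#' Dice similarity coefficient
#'
#' `2 |X n Y| / (|X| + |Y|)` on aligned binary masks; two empty masks score
#' 1 by convention.
#'
#' @param X,Y [label_volume()]s (or plain binary rank-3 arrays) of
#'   identical shape.
#' @return Fraction in `[0, 1]`.
#' @export
dsc <- function(X, Y) {
  mx <- if (inherits(X, "label_volume")) X$mask else X
  my <- if (inherits(Y, "label_volume")) Y$mask else Y
  if (!identical(dim(mx), dim(my)))
    stop("mask shapes differ: ", paste(dim(mx), collapse = "x"), " vs ",
         paste(dim(my), collapse = "x"))
  denom <- sum(mx) + sum(my)
  if (denom == 0) return(1)
  2 * sum(mx * my) / denom
}

#' Per-case evaluation record
#'
#' @param case_id case identifier.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param dsc Dice coefficient in `[0, 1]`.
#' @param method method label (e.g. `"unet3d+ps"`).
#' @param train_domain,test_domain domain tags (`"real_A"`, `"fake_B"`,
#'   `"real_B"`).
#' @return One-row tibble.
#' @export
case_result <- function(case_id, vessel_class, dsc, method = "unet3d",
                        train_domain = "real_B", test_domain = "real_B") {
  stopifnot(dsc >= 0, dsc <= 1)
  tibble::tibble(case_id = case_id, vessel_class = vessel_class, dsc = dsc,
                 method = method, train_domain = train_domain,
                 test_domain = test_domain)
}

#' Summarize case results into a mean +/- sd table
#'
#' Groups by (method, train_domain, test_domain, vessel_class) and reports
#' the group mean and sample (n-1) standard deviation, mirroring the
#' "Average DSC" reporting convention.
#'
#' @param results tibble of rows from [case_result()].
#' @return Tibble with columns `method`, `train_domain`, `test_domain`,
#'   `vessel_class`, `n`, `mean_dsc`, `sd_dsc`, `label`.
#' @export
summarize_results <- function(results) {
  if (nrow(results) == 0) stop("no case results to summarize")
  dplyr::summarise(
    dplyr::group_by(results, .data$method, .data$train_domain,
                    .data$test_domain, .data$vessel_class),
    n = dplyr::n(),
    mean_dsc = mean(.data$dsc),
    sd_dsc = ifelse(dplyr::n() > 1, stats::sd(.data$dsc), 0),
    .groups = "drop") |>
    dplyr::mutate(label = sprintf("%.4f ± %.4f", .data$mean_dsc,
                                  .data$sd_dsc))
}

#' Plot a stage-1 training log
#'
#' @param object a `vra_log` tibble from [train_vra()].
#' @param ... unused.
#' @return A ggplot of the loss terms against training step.
#' @export
autoplot.vra_log <- function(object, ...) {
  long <- tidyr_pivot(object, c("l_cycle", "l_adv", "l_local", "l_idt"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stage-2 training log
#'
#' @param object a `seg_log` tibble from [train_seg()].
#' @param ... unused.
#' @return A ggplot of Dice and projection losses per step.
#' @export
autoplot.seg_log <- function(object, ...) {
  object$step_global <- seq_len(nrow(object))
  long <- tidyr_pivot(object, c("dice", "ps"), step_col = "step_global")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step_global, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# base-R long pivot (keeps tidyr out of Imports for one call site)
tidyr_pivot <- function(df, cols, step_col = "step") {
  dplyr::bind_rows(lapply(cols, function(cn)
    tibble::tibble(step = df[[step_col]], term = cn, value = df[[cn]])))
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Run the train/test-domain experiment grid on phantom data
#'
#' Phantom-scale analogue of the arterial cross-domain comparison: a 3D
#' U-Net is trained (a) on native arterial-phase volumes, (b) on translated
#' pseudo-venous volumes without the projection loss, and (c) with it, and
#' each model is evaluated on both its own training domain and on real
#' venous-phase volumes (artery ground truth in venous geometry).
#'
#' @param train_cases,test_cases lists of phantom cases from
#'   [phantom_case()], preprocessed to normalized units by the caller.
#' @param translate function mapping a normalized arterial [ct_volume()] to
#'   its pseudo-venous translation (e.g. a trained `function(v)
#'   translate_volume(G, v)`); identity for the "real A" rows.
#' @param config a [seg_config()].
#' @return Tibble of [case_result()] rows for every (method, domain)
#'   combination.
#' @export
run_phantom_grid <- function(train_cases, test_cases, translate,
                             config = seg_config()) {
  rows <- list()
  eval_model <- function(net, method, train_domain) {
    for (cs in test_cases) {
      for (dom in c("train", "real_B")) {
        vol <- switch(dom,
                      train = if (train_domain == "real_A") cs$vol_a
                              else translate(cs$vol_a),
                      real_B = cs$vol_b)
        truth <- if (dom == "real_B") cs$artery_b else cs$label_a
        pred <- predict_volume(net, vol, vessel_class = "artery")
        rows[[length(rows) + 1L]] <<- case_result(
          vol$case_id, "artery", dsc(pred, truth), method = method,
          train_domain = train_domain,
          test_domain = if (dom == "real_B") "real_B" else train_domain)
      }
    }
  }
  ds_a <- lapply(train_cases, function(cs)
    list(volume = cs$vol_a, label = cs$label_a))
  ds_fb <- lapply(train_cases, function(cs)
    list(volume = translate(cs$vol_a), label = cs$label_a))

  cfg0 <- config; cfg0$lambda_ps <- 0
  eval_model(train_seg(ds_a, cfg0)$net, "unet3d", "real_A")
  eval_model(train_seg(ds_fb, cfg0)$net, "unet3d", "fake_B")
  eval_model(train_seg(ds_fb, config)$net, "unet3d+ps", "fake_B")
  dplyr::bind_rows(rows)
}
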