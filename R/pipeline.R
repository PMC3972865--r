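#' Select the enhanced image from a decomposition by the contrast criterion
#'
#' Computes the direction-averaged co-occurrence contrast for every intrinsic
#' mode function, the residue, and the original (reconstructed) image, and
#' selects the IMF with the greatest contrast.  For micrograph-like inputs
#' the contrast ordering is IMF1 > IMF2 > ... > residue, so the selection is
#' IMF1; using the argmax rather than hard-coding IMF1 lets the method
#' degrade gracefully when noise does not dominate the top band.
#'
#' @param decomposition a `bemd_result` from [bemd()].
#' @param config a [glcm_config()] used for the contrast measurements.
#' @return list with `selected` (matrix), `selected_label`, and `table`
#'   (class `contrast_table`: data frame with columns `label`, `contrast`,
#'   one row per IMF plus `residue` and `original`).
#' @export
select_enhanced_image <- function(decomposition, config = glcm_config()) {
  if (!inherits(decomposition, "bemd_result"))
    stop_validation("decomposition must be a bemd_result")
  original <- bemd_reconstruct(decomposition)
  L <- length(decomposition$imfs)
  images <- c(decomposition$imfs, list(decomposition$residue, original))
  labels <- c(if (L > 0) paste0("IMF", seq_len(L)), "residue", "original")
  contrast <- vapply(images, function(im) {
    mean_direction_contrast(im, config)
  }, numeric(1))
  tab <- structure(data.frame(label = labels, contrast = contrast),
                   class = c("contrast_table", "data.frame"))
  if (L == 0L) {
    warning("empty decomposition: falling back to the original image")
    return(list(selected = original, selected_label = "original", table = tab))
  }
  best <- which.max(contrast[seq_len(L)])
  list(selected = decomposition$imfs[[best]],
       selected_label = labels[best], table = tab)
}

# direction-averaged GLCM contrast of one image (quantized to config$levels)
mean_direction_contrast <- function(image, config) {
  q <- quantize(image, config$levels)
  mean(vapply(config$directions, function(theta) {
    glcm_contrast(compute_glcm(q, distance = config$distance,
                               direction = theta,
                               symmetric = config$symmetric,
                               levels = config$levels))
  }, numeric(1)))
}

#' Run the full enhancement-plus-texture pipeline on one image
#'
#' Decomposes the image ([bemd()]), selects the sharpest component by the
#' contrast criterion ([select_enhanced_image()]), and extracts the five
#' texture features in four directions ([extract_features()]) from the
#' selection.  The contrast table is attached to the result as attribute
#' `contrast_table` and the selection label as `selected_label`.
#'
#' @param image numeric matrix, at least 8 x 8.
#' @param sift_config a [sift_config()].
#' @param glcm_config a [glcm_config()].
#' @return a `texture_features` object (see [extract_features()]).
#' @export
analyze_image <- function(image, sift_config = mttex::sift_config(),
                          glcm_config = mttex::glcm_config()) {
  dec <- bemd(image, sift_config)
  sel <- if (length(dec$imfs) == 0L) {
    warning("decomposition produced no IMFs: analyzing the original image")
    list(selected = bemd_reconstruct(dec), selected_label = "original",
         table = NULL)
  } else {
    select_enhanced_image(dec, glcm_config)
  }
  feats <- extract_features(sel$selected, glcm_config)
  attr(feats, "contrast_table") <- sel$table
  attr(feats, "selected_label") <- sel$selected_label
  feats
}

# coerce a group (list of texture_features, or a data frame / matrix of
# per-image feature values) to a numeric matrix, one row per image
feature_matrix <- function(group, features) {
  if (is.data.frame(group) || is.matrix(group)) {
    m <- as.matrix(group)
    missing <- setdiff(features, colnames(m))
    if (length(missing))
      stop_validation("group lacks feature columns: ",
                      paste(missing, collapse = ", "))
    return(m[, features, drop = FALSE])
  }
  if (!is.list(group) || !all(vapply(group, inherits, logical(1),
                                     "texture_features")))
    stop_validation("group must be a list of texture_features or a data frame")
  do.call(rbind, lapply(group, function(f) f$mean[features]))
}

group_config <- function(group) {
  if (is.list(group) && length(group) &&
      inherits(group[[1L]], "texture_features")) group[[1L]]$config else NULL
}

#' Compare texture features between two groups of images
#'
#' For each requested feature, reduces every image to one scalar (the mean
#' over the four directions), then runs a two-sample two-sided t-test between
#' the groups: Welch's unequal-variance test by default (it coincides with
#' Student's under equal variances), pooled-variance Student optional.
#' Reports group means and SDs alongside the test.  If both groups have zero
#' within-group variance the test is decided by convention: equal means give
#' `t = 0, p = 1`, different means `p = 0`.
#'
#' @param group_a,group_b lists of `texture_features` (from [analyze_image()]
#'   or [extract_features()]), or data frames of per-image feature values.
#'   At least 3 images per group.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param features which features to test; the default is the four used for
#'   arrangement discrimination (contrast serves as the enhancement criterion
#'   instead).
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for pooled Student.
#' @param p_adjust multiple-testing correction across features
#'   (see [stats::p.adjust()]); `"none"` by default.
#' @return object of class `group_comparison`: data frame with one row per
#'   feature (means, SDs, sizes, `t`, `df`, `p_value`, `significant`);
#'   attributes `alpha` and `method`.
#' @export
compare_groups <- function(group_a, group_b, alpha = 0.05,
                           features = c("asm", "entropy", "idm", "variance"),
                           var_equal = FALSE, p_adjust = "none") {
  ca <- group_config(group_a); cb <- group_config(group_b)
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop_validation("groups were computed under different GLCM configs")
  A <- feature_matrix(group_a, features)
  B <- feature_matrix(group_b, features)
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop_validation("each group needs at least 3 images")
  rows <- lapply(features, function(f) {
    a <- A[, f]; b <- B[, f]
    if (sd(a) == 0 && sd(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                 parameter = NA_real_, p.value = if (eq) 1 else 0)
    } else {
      ht <- t.test(a, b, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(feature = f,
               mean_a = mean(a), sd_a = sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = sd(b), n_b = length(b),
               t = tt$statistic, df = tt$parameter, p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  structure(out,
            class = c("group_comparison", "data.frame"),
            alpha = alpha,
            method = if (var_equal) "Student t (pooled)" else "Welch t")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(attr(x, "method"), "two-sided comparison, alpha =",
      attr(x, "alpha"), "\n")
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 4)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 5)
  print(df, row.names = FALSE)
  invisible(x)
}
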