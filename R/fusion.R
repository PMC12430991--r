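# Decision-level fusion: the Sf rule, the three-tier online logic, and the
# nearest-centroid three-class stress classifier.

#' Fusion rule parameters
#'
#' Defaults mirror the baseline rule system: `Sf = alpha*Sb + beta*Sp` with
#' `alpha = 1`, `beta = 1.5` and an inclusive trigger at `Sf >= 3`; tier-2
#' selective fusion `S = w_b*B + w_g*Gnorm` with weights 0.6/0.4 and a
#' strict alert threshold `S > 0.65`; tier-1 immediate alert on GSR level
#' strictly above 0.7 uS or dominant tremor frequency strictly above 30 Hz.
#'
#' @param alpha Weight on the behavioral score Sb.
#' @param beta Weight on the physiological flag Sp.
#' @param trigger Sf trigger threshold (inclusive).
#' @param w_b,w_g Tier-2 weights on B and Gnorm.
#' @param s_thresh Tier-2 alert threshold (strict).
#' @param tier1_gsr Tier-1 GSR level threshold, uS (strict).
#' @param tier1_tremor_freq Tier-1 dominant tremor frequency threshold, Hz
#'   (strict).
#' @return A `fusion_params` list.
#' @export
fusion_params <- function(alpha = 1, beta = 1.5, trigger = 3,
                          w_b = 0.6, w_g = 0.4, s_thresh = 0.65,
                          tier1_gsr = 0.7, tier1_tremor_freq = 30) {
  p <- list(alpha = alpha, beta = beta, trigger = trigger, w_b = w_b,
            w_g = w_g, s_thresh = s_thresh, tier1_gsr = tier1_gsr,
            tier1_tremor_freq = tier1_tremor_freq)
  if (alpha < 0 || beta < 0 || w_b < 0 || w_g < 0) {
    stop("fusion weights must be nonnegative", call. = FALSE)
  }
  if (trigger <= 0 || s_thresh <= 0 || tier1_gsr <= 0 || tier1_tremor_freq <= 0) {
    stop("fusion thresholds must be strictly positive", call. = FALSE)
  }
  structure(p, class = "fusion_params")
}

#' Fused stress score Sf
#'
#' `Sf = alpha*Sb + beta*Sp`; a stress state is triggered when
#' `Sf >= trigger` (inclusive). With the defaults this is exactly the set
#' \{Sb >= 3\} united with \{Sb >= 2 and Sp = 1\}: mild behavioral signs
#' need the GSR rise to qualify as stress.
#'
#' @param Sb Behavioral score(s), integers in 0–4.
#' @param Sp Physiological flag(s), 0 or 1.
#' @param params A [fusion_params()] list.
#' @return A tibble with columns `Sb, Sp, Sf, stress` (vectorized).
#' @export
fuse <- function(Sb, Sp, params = fusion_params()) {
  if (!all(Sb %in% 0:4)) stop("Sb must be an integer in 0..4", call. = FALSE)
  if (!all(Sp %in% c(0, 1))) stop("Sp must be binary (0/1)", call. = FALSE)
  Sf <- params$alpha * Sb + params$beta * Sp
  tibble::tibble(Sb = as.integer(Sb), Sp = as.integer(Sp), Sf = Sf,
                 stress = Sf >= params$trigger)
}

#' Normalized behavioral score B
#'
#' Maps Sb from its 0–4 range onto `[0, 1]` as `B = Sb/4`, the form used by
#' the tier-2 fusion score.
#'
#' @param Sb Behavioral score(s), integers in 0–4.
#' @return `B` in `[0, 1]`.
#' @export
normalized_behavior <- function(Sb) {
  if (!all(Sb %in% 0:4)) stop("Sb must be an integer in 0..4", call. = FALSE)
  Sb / 4
}

#' Three-tier stress decision
#'
#' Tier 1 (immediate alert): a single overwhelming signal — dominant tremor
#' frequency strictly above `tier1_tremor_freq` or GSR level strictly above
#' `tier1_gsr`. Tier 2 (selective fusion): otherwise compute
#' `S = w_b*B + w_g*Gnorm` and alert iff `S > s_thresh` (strict); with GSR
#' absent, `S = B` alone. Tier 3: no alert, the system stays idle.
#' The fused score `Sf` and its inclusive trigger are reported alongside.
#'
#' @param behavior A one-row tibble or list with the four binary indicator
#'   flags (`hesitation_flag`, `error_flag`, `inactivity_flag`,
#'   `tremor_flag`) and `tremor_freq_hz` (may be `NA`).
#' @param gsr A one-row [gsr_state()] tibble, or `NULL` in behavior-only
#'   mode.
#' @param params A [fusion_params()] list.
#' @return A one-row tibble: `Sb, Sp, B, Gnorm, Sf, stress, tier, S, alert,
#'   reason`.
#' @export
tier_decision <- function(behavior, gsr = NULL, params = fusion_params()) {
  Sb <- behavioral_score(behavior$hesitation_flag, behavior$error_flag,
                         behavior$inactivity_flag, behavior$tremor_flag)
  B <- normalized_behavior(Sb)
  Sp <- if (is.null(gsr)) 0L else as.integer(gsr$Sp)
  Gnorm <- if (is.null(gsr)) NA_real_ else gsr$Gnorm
  fused <- fuse(Sb, Sp, params)
  tremor_freq <- behavior$tremor_freq_hz
  tier1_tremor <- !is.na(tremor_freq) && tremor_freq > params$tier1_tremor_freq
  tier1_gsr <- !is.null(gsr) && !is.na(gsr$level) && gsr$level > params$tier1_gsr
  if (tier1_tremor || tier1_gsr) {
    tier <- 1L
    S <- NA_real_
    alert <- TRUE
    reason <- if (tier1_gsr && tier1_tremor) "tier1: GSR level and tremor frequency"
              else if (tier1_gsr) "tier1: GSR level above threshold"
              else "tier1: tremor frequency above threshold"
  } else {
    S <- if (is.null(gsr) || is.na(Gnorm)) B else params$w_b * B + params$w_g * Gnorm
    if (S > params$s_thresh) {
      tier <- 2L
      alert <- TRUE
      reason <- sprintf("tier2: fusion score S = %.3f above threshold", S)
    } else {
      tier <- 3L
      alert <- FALSE
      reason <- "tier3: all indicators within normal bounds"
    }
  }
  tibble::tibble(Sb = Sb, Sp = Sp, B = B, Gnorm = Gnorm, Sf = fused$Sf,
                 stress = fused$stress, tier = tier, S = S, alert = alert,
                 reason = reason)
}

#' Class centroids for the three-class rule classifier
#'
#' The default centroids are the per-class medians of hesitation time (s),
#' tremble amplitude (tracker units) and GSR (uS); the per-feature scales
#' are the spans of the class medians, so each feature contributes
#' comparably to the distance.
#'
#' @param centroids Tibble with columns `class, hesitation_s,
#'   tremble_units, gsr_uS`, one row per class.
#' @param scales Named positive numeric vector of per-feature scales.
#' @return A `class_centroids` object.
#' @export
class_centroids <- function(centroids = NULL, scales = NULL) {
  if (is.null(centroids)) {
    centroids <- tibble::tibble(
      class = c("Negative", "Neutral", "Positive"),
      hesitation_s = c(0.99, 1.69, 0.91),
      tremble_units = c(0.0060, 0.0160, 0.0050),
      gsr_uS = c(0.62, 0.77, 0.61)
    )
  }
  centroids <- tibble::as_tibble(centroids)
  stopifnot(all(c("class", "hesitation_s", "tremble_units", "gsr_uS") %in%
                  names(centroids)),
            nrow(centroids) == 3)
  if (is.null(scales)) {
    scales <- vapply(c("hesitation_s", "tremble_units", "gsr_uS"),
                     function(f) diff(range(centroids[[f]])), numeric(1))
  }
  if (any(scales <= 0)) stop("centroid scales must be > 0", call. = FALSE)
  structure(list(centroids = centroids, scales = scales),
            class = "class_centroids")
}

#' Nearest-centroid three-class stress classifier
#'
#' Assigns each trial to the class whose centroid is nearest under the
#' per-feature scaled Euclidean distance (each feature divided by its
#' scale). Exact ties go to `Neutral`. The per-class scores (negative
#' scaled distances) are returned for ROC ranking.
#'
#' @param features Tibble with columns `hesitation_s, tremble_units,
#'   gsr_uS` (finite).
#' @param centroids A [class_centroids()] object.
#' @return `features` with `pred` (factor over the three classes) and score
#'   columns `score_Negative, score_Neutral, score_Positive` appended.
#' @export
classify3 <- function(features, centroids = class_centroids()) {
  features <- tibble::as_tibble(features)
  feat_cols <- c("hesitation_s", "tremble_units", "gsr_uS")
  stopifnot(all(feat_cols %in% names(features)))
  X <- as.matrix(features[feat_cols])
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  sc <- centroids$scales[feat_cols]
  Xs <- sweep(X, 2, sc, "/")
  C <- as.matrix(centroids$centroids[feat_cols])
  Cs <- sweep(C, 2, sc, "/")
  D <- sapply(seq_len(nrow(Cs)), function(k) {
    sqrt(rowSums(sweep(Xs, 2, Cs[k, ], "-")^2))
  })
  D <- matrix(D, nrow = nrow(Xs))
  classes <- centroids$centroids$class
  pred <- apply(D, 1, function(d) {
    winners <- classes[d == min(d)]
    if (length(winners) > 1) "Neutral" else winners
  })
  scores <- -D
  colnames(scores) <- paste0("score_", classes)
  dplyr::bind_cols(features,
                   tibble::tibble(pred = factor(pred, levels = CLASS_LEVELS)),
                   tibble::as_tibble(scores))
}
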