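#' Build a synthetic participant roster
#'
#' Generates `n_total` participant records with demographics drawn from the
#' configured distributions, of which `n_incomplete` are flagged as not
#' having completed the study (the defaults mirror the acquisition sample:
#' 153 recruited, 3 incomplete, hence 150 analyzable, about 65% female,
#' age mean 26.16 and SD 9.137 truncated at 18). Attitude ("My attitude
#' today is ...") and self-esteem ("I have high self-esteem") are sampled
#' independently of everything else. Deterministic per seed.
#'
#' @param n_total participants recruited.
#' @param n_incomplete participants flagged `completed = FALSE`.
#' @param demographics list overriding any of `p_female`, `age_mean`,
#'   `age_sd`, `attitude_probs` (length 3), `self_esteem_probs` (length 5).
#' @param rng_seed integer seed.
#' @return data.frame with columns `id`, `sex`, `age`, `attitude`,
#'   `self_esteem`, `completed`.
#' @export
make_roster <- function(n_total = 153L, n_incomplete = 3L,
                        demographics = list(), rng_seed = 1L) {
  if (n_incomplete < 0 || n_incomplete > n_total)
    stop("need 0 <= n_incomplete <= n_total", call. = FALSE)
  dem <- utils::modifyList(list(
    p_female = 98 / 150, age_mean = 26.16, age_sd = 9.137,
    attitude_probs = c(Positive = 0.5, Neutral = 0.35, Negative = 0.15),
    self_esteem_probs = c("Definitely true" = 0.2, "Probably true" = 0.35,
                          "Neither true nor false" = 0.2,
                          "Probably false" = 0.15,
                          "Definitely false" = 0.1)), demographics)
  if (n_total == 0L)
    return(data.frame(id = character(), sex = character(), age = numeric(),
                      attitude = character(), self_esteem = character(),
                      completed = logical(), stringsAsFactors = FALSE))
  withr::with_seed(rng_seed, {
    sex <- sample(c("female", "male"), n_total, replace = TRUE,
                  prob = c(dem$p_female, 1 - dem$p_female))
    age <- pmax(18, round(stats::rnorm(n_total, dem$age_mean, dem$age_sd)))
    attitude <- sample(names(dem$attitude_probs), n_total, replace = TRUE,
                       prob = dem$attitude_probs)
    self_esteem <- sample(names(dem$self_esteem_probs), n_total,
                          replace = TRUE, prob = dem$self_esteem_probs)
    incomplete <- sample(n_total, n_incomplete)
  })
  data.frame(id = sprintf("P%03d", seq_len(n_total)), sex = sex, age = age,
             attitude = attitude, self_esteem = self_esteem,
             completed = !seq_len(n_total) %in% incomplete,
             stringsAsFactors = FALSE)
}

#' Assign layer groups, image seeds and presentation order
#'
#' Partitions the layer inventory into `n_groups` equal disjoint groups
#' (contiguous blocks by default, random partition optionally), assigns each
#' participant one group uniformly at random, draws for each (participant,
#' layer) slot one image seed uniformly from `0 ... n_images - 1`, and a
#' uniform random presentation order per participant. With the 144-layer
#' inventory and 3 groups every participant receives exactly 48 slots.
#'
#' @param inventory character vector of layer names; its length must be
#'   divisible by `n_groups`.
#' @param roster data.frame from [make_roster()].
#' @param n_groups number of layer groups (default 3).
#' @param n_images images (noise seeds) available per layer (default 5).
#' @param rng_seed integer seed.
#' @param partition `"blocks"` (default, deterministic contiguous split) or
#'   `"random"`.
#' @return list with `layer_groups` (list of character vectors) and `slots`
#'   (data.frame: participant_id, group, layer_name, seed_index,
#'   presentation_order).
#' @export
assign_groups <- function(inventory, roster, n_groups = 3L, n_images = 5L,
                          rng_seed = 1L, partition = c("blocks", "random")) {
  partition <- match.arg(partition)
  n_layers <- length(inventory)
  if (n_layers %% n_groups != 0L)
    stop(sprintf("inventory size %d is not divisible into %d equal groups",
                 n_layers, n_groups), call. = FALSE)
  per <- n_layers %/% n_groups
  withr::with_seed(rng_seed, {
    ord <- if (partition == "random") sample(n_layers) else seq_len(n_layers)
    layer_groups <- split(inventory[ord], rep(seq_len(n_groups), each = per))
    names(layer_groups) <- paste0("group", seq_len(n_groups))
    grp <- sample(n_groups, nrow(roster), replace = TRUE)
    slots <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
      lays <- layer_groups[[grp[i]]]
      data.frame(participant_id = roster$id[i], group = grp[i],
                 layer_name = lays,
                 seed_index = sample(0:(n_images - 1L), per, replace = TRUE),
                 presentation_order = sample(per),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(slots) <- NULL
  list(layer_groups = layer_groups, slots = slots)
}

#' Effect specification for the rating simulator
#'
#' Defines the generating model for arousal and valence responses: a linear
#' effect of the six image features plus a Gaussian participant random
#' intercept and Gaussian residual noise, optionally overridden for named
#' layers by a two-component mixture in the arousal-valence plane (to
#' emulate polarized responses). Exactly one of `residual_sd` or
#' `target_r2` must be supplied; `target_r2` is converted to a residual SD
#' at simulation time via [rsq_to_noise_sd()]. Scalars given for
#' per-scale fields are recycled to both scales.
#'
#' @param arousal_beta,valence_beta named numeric coefficients per feature.
#' @param intercept expected rating at zero features; length 1 or 2
#'   (arousal, valence). Default 50.
#' @param participant_sd SD of the participant random intercept.
#' @param residual_sd residual SD, length 1 or 2; mutually exclusive with
#'   `target_r2`.
#' @param target_r2 population R-squared of the feature effect, length 1 or
#'   2, each in \code{[0, 1)}.
#' @param bimodal_layers optional named list: layer ->
#'   `list(mode1 = c(arousal, valence), mode2 = c(arousal, valence),
#'   weight, sd)`.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(arousal_beta, valence_beta = arousal_beta,
                        intercept = 50, participant_sd = 0,
                        residual_sd = NULL, target_r2 = NULL,
                        bimodal_layers = NULL) {
  if (is.null(residual_sd) == is.null(target_r2))
    stop("supply exactly one of residual_sd or target_r2", call. = FALSE)
  if (!is.null(residual_sd)) stopifnot(all(residual_sd >= 0))
  if (!is.null(target_r2)) stopifnot(all(target_r2 >= 0), all(target_r2 < 1))
  if (!is.null(bimodal_layers))
    for (bl in bimodal_layers)
      stopifnot(bl$weight > 0, bl$weight < 1,
                length(bl$mode1) == 2L, length(bl$mode2) == 2L)
  recycle2 <- function(x) if (length(x) == 1L) c(x, x) else x
  structure(list(arousal_beta = arousal_beta, valence_beta = valence_beta,
                 intercept = recycle2(intercept),
                 participant_sd = participant_sd,
                 residual_sd = if (!is.null(residual_sd)) recycle2(residual_sd),
                 target_r2 = if (!is.null(target_r2)) recycle2(target_r2),
                 bimodal_layers = bimodal_layers),
            class = "effect_spec")
}

#' Residual SD that yields a target population R-squared
#'
#' Closed-form calibration: with linear predictor variance
#' `v = Var(X beta)` computed empirically over the feature table, the
#' residual SD `sigma = sqrt(v * (1 - R2) / R2)` makes the generating
#' model's population R-squared equal to `target_r2`.
#'
#' @param beta named numeric coefficient vector.
#' @param feature_table data.frame containing the columns named in `beta`.
#' @param target_r2 desired population R-squared in (0, 1).
#' @return residual standard deviation (scalar).
#' @export
rsq_to_noise_sd <- function(beta, feature_table, target_r2) {
  stopifnot(target_r2 >= 0, target_r2 < 1)
  X <- as.matrix(feature_table[, names(beta), drop = FALSE])
  eta <- drop(X %*% beta)
  if (target_r2 == 0) {
    if (any(beta != 0))
      stop("target_r2 = 0 requires zero coefficients; supply residual_sd directly",
           call. = FALSE)
    stop("target_r2 = 0 leaves the residual SD free; supply residual_sd directly",
         call. = FALSE)
  }
  v <- stats::var(eta)
  if (v == 0) stop("degenerate features: Var(X beta) = 0", call. = FALSE)
  sqrt(v * (1 - target_r2) / target_r2)
}

#' Simulate slider ratings for an assignment
#'
#' For every (participant, layer, seed) slot, draws arousal and valence as
#' `intercept + X beta + participant intercept + N(0, residual_sd)`, using
#' the features of the assigned (layer, seed) image, then clips to
#' \code{[0, 100]} (slider semantics). The clipped fraction is recorded in
#' the `clipped_fraction` attribute and a warning is raised if it exceeds
#' 1%. Layers named in `bimodal_layers` instead draw from the specified
#' two-component Gaussian mixture in the arousal-valence plane. Incomplete
#' participants in `roster` (if given) are truncated to a random prefix of
#' their presentation order. Deterministic per seed.
#'
#' @param assignment result of [assign_groups()].
#' @param feature_table data.frame with `layer`, `seed` and the feature
#'   columns named in the effect's beta vectors.
#' @param effect an [effect_spec()].
#' @param rng_seed integer seed.
#' @param roster optional roster; incomplete participants rate fewer images.
#' @return data.frame of ratings: `participant_id`, `layer_name`,
#'   `seed_index`, `arousal`, `valence`, `presentation_order`, with
#'   attributes `clipped_fraction` and `rng_seed`.
#' @export
simulate_ratings <- function(assignment, feature_table, effect,
                             rng_seed = 1L, roster = NULL) {
  stopifnot(inherits(effect, "effect_spec"))
  slots <- assignment$slots
  key <- paste(slots$layer_name, slots$seed_index)
  fkey <- paste(feature_table$layer, feature_table$seed)
  miss <- !key %in% fkey
  if (any(miss))
    stop("features missing for pairs: ",
         paste(unique(key[miss]), collapse = ", "), call. = FALSE)
  rows <- match(key, fkey)
  Xa <- as.matrix(feature_table[rows, names(effect$arousal_beta), drop = FALSE])
  Xv <- as.matrix(feature_table[rows, names(effect$valence_beta), drop = FALSE])
  sd_res <- effect$residual_sd %||% c(
    rsq_to_noise_sd(effect$arousal_beta, feature_table, effect$target_r2[1]),
    rsq_to_noise_sd(effect$valence_beta, feature_table, effect$target_r2[2]))
  ids <- unique(slots$participant_id)
  withr::with_seed(rng_seed, {
    pa <- stats::setNames(stats::rnorm(length(ids), 0, effect$participant_sd), ids)
    pv <- stats::setNames(stats::rnorm(length(ids), 0, effect$participant_sd), ids)
    arousal <- effect$intercept[1] + drop(Xa %*% effect$arousal_beta) +
      pa[slots$participant_id] + stats::rnorm(nrow(slots), 0, sd_res[1])
    valence <- effect$intercept[2] + drop(Xv %*% effect$valence_beta) +
      pv[slots$participant_id] + stats::rnorm(nrow(slots), 0, sd_res[2])
    for (lay in names(effect$bimodal_layers %||% list())) {
      bl <- effect$bimodal_layers[[lay]]
      sel <- which(slots$layer_name == lay)
      if (!length(sel)) next
      comp <- stats::rbinom(length(sel), 1L, bl$weight)
      mu <- rbind(bl$mode2, bl$mode1)[comp + 1L, , drop = FALSE]
      sdm <- bl$sd %||% 8
      arousal[sel] <- mu[, 1] + stats::rnorm(length(sel), 0, sdm)
      valence[sel] <- mu[, 2] + stats::rnorm(length(sel), 0, sdm)
    }
    keep <- rep(TRUE, nrow(slots))
    if (!is.null(roster)) {
      for (id in roster$id[!roster$completed]) {
        n_rated <- sample(0:(sum(slots$participant_id == id) - 1L), 1L)
        keep[slots$participant_id == id &
               slots$presentation_order > n_rated] <- FALSE
      }
    }
  })
  clipped <- mean(arousal < 0 | arousal > 100 | valence < 0 | valence > 100)
  if (clipped > 0.01)
    warning(sprintf("%.1f%% of ratings clipped to [0, 100]", 100 * clipped),
            call. = FALSE)
  out <- data.frame(participant_id = slots$participant_id,
                    layer_name = slots$layer_name,
                    seed_index = slots$seed_index,
                    arousal = clip_range(arousal, 0, 100),
                    valence = clip_range(valence, 0, 100),
                    presentation_order = slots$presentation_order,
                    stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  attr(out, "clipped_fraction") <- clipped
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Retain complete participants
#'
#' Keeps participants flagged `completed` who contributed the full set of
#' `n_required` ratings; others are dropped with a message.
#'
#' @param roster data.frame from [make_roster()].
#' @param ratings data.frame of ratings keyed by `participant_id`.
#' @param n_required ratings required for a complete record (default 48).
#' @return the retained subset of `roster`.
#' @export
filter_complete <- function(roster, ratings, n_required = 48L) {
  counts <- table(ratings$participant_id)
  n_rated <- as.integer(counts[roster$id])
  n_rated[is.na(n_rated)] <- 0L
  keep <- roster$completed & n_rated == n_required
  dropped <- roster$id[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " incomplete participant(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  out <- roster[keep, ]
  rownames(out) <- NULL
  out
}
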