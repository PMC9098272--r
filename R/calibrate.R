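#' Closed-form trainable-parameter count for a model configuration
#'
#' Mirrors the parameter inventory of [build_model()]: block-1 temporal and
#' spatial convolutions with two batch norms, three separable blocks, two
#' ConvLSTM directions (three dense gates plus the convolutional candidate
#' path, hidden width `D*F4`), attention, and the biased classifier. The
#' test suite asserts this formula against direct enumeration of an
#' initialized model.
#'
#' @param C electrode channels.
#' @param F1,F2,F3,F4 block filter counts.
#' @param D depth multiplier.
#' @param candidate_kernel ConvLSTM candidate kernel length.
#' @param attention_dim attention key dimension.
#' @param n_classes output classes.
#' @param temporal_kernel,separable_kernel backbone kernel lengths.
#' @param use_recurrent_head include the BiConvLSTM + attention head.
#' @return integer parameter count.
#' @export
parameter_count_formula <- function(C = 22L, F1 = 8L, F2 = 16L, F3 = 32L,
                                    F4 = 32L, D = 1L, candidate_kernel = 3L,
                                    attention_dim = 26L, n_classes = 4L,
                                    temporal_kernel = 64L,
                                    separable_kernel = 16L,
                                    use_recurrent_head = TRUE) {
  m1 <- D * F1
  backbone <- temporal_kernel * F1 + 2 * F1 +          # conv_time + BN
    C * m1 + 2 * m1 +                                  # conv_spat + BN
    separable_kernel * m1 + m1 * F2 + 2 * F2 +         # block 2
    separable_kernel * F2 + F2 * F3 + 2 * F3 +         # block 3
    separable_kernel * F3 + F3 * F4 + 2 * F4           # block 4
  m <- D * F4
  if (use_recurrent_head) {
    per_dir <- 3 * (2 * m * m + m) + 2 * candidate_kernel + m
    head <- 2 * per_dir + attention_dim * (2 * m + 2)
    cls <- n_classes * (2 * m + 1)
  } else {
    head <- 0
    cls <- n_classes * (m + 1)
  }
  as.integer(backbone + head + cls)
}

#' Calibrate the unprinted architecture hyperparameters
#'
#' The filter counts F1--F4 and the recurrent hidden width are fixed only
#' through the published total of 17,972 trainable parameters. This search
#' enumerates small filter ladders (powers of two and near neighbors up to
#' 64) and candidate kernels, keeping every configuration whose
#' [parameter_count_formula()] hits the target exactly with an admissible
#' attention dimension. Preference order among exact solutions: monotone
#' non-decreasing power-of-two ladders with candidate kernel 3, then the
#' widest ladder (most feature capacity), then the most doubling steps. The
#' hidden width is tied to `D*F4` by the candidate-path convolution, so it
#' is calibrated implicitly.
#'
#' @param target total trainable-parameter count to match.
#' @param C electrode channels.
#' @param n_classes output classes.
#' @param filter_candidates admissible per-block filter counts.
#' @param kernel_candidates admissible candidate-convolution kernels.
#' @param max_attention_dim largest admissible attention key dimension.
#' @return a tibble of exact solutions (columns F1..F4, candidate_kernel,
#'   attention_dim, hidden, n_parameters, preferred), best first.
#' @export
calibrate_architecture <- function(target = 17972L, C = 22L, n_classes = 4L,
                                   filter_candidates = c(2L, 4L, 6L, 8L, 12L,
                                                         16L, 24L, 32L, 48L, 64L),
                                   kernel_candidates = c(3L, 5L),
                                   max_attention_dim = 64L) {
  grid <- expand.grid(F1 = filter_candidates, F2 = filter_candidates,
                      F3 = filter_candidates, F4 = filter_candidates,
                      k = kernel_candidates)
  sols <- purrr::pmap_dfr(grid, function(F1, F2, F3, F4, k) {
    # solve for the attention dimension: it enters the count linearly
    base <- parameter_count_formula(C, F1, F2, F3, F4, 1L, k,
                                    attention_dim = 0L, n_classes = n_classes)
    rest <- target - base
    slope <- 2L * F4 + 2L
    if (rest <= 0 || rest %% slope != 0) return(NULL)
    a <- rest %/% slope
    if (a < 1 || a > max_attention_dim) return(NULL)
    tibble::tibble(F1 = F1, F2 = F2, F3 = F3, F4 = F4,
                   candidate_kernel = k, attention_dim = as.integer(a),
                   hidden = F4,
                   n_parameters = parameter_count_formula(
                     C, F1, F2, F3, F4, 1L, k, as.integer(a), n_classes))
  })
  if (nrow(sols) == 0) return(sols)
  pow2 <- function(x) x > 0 & bitwAnd(x, x - 1L) == 0L
  sols <- dplyr::mutate(
    sols,
    monotone = F1 <= F2 & F2 <= F3 & F3 <= F4,
    all_pow2 = pow2(F1) & pow2(F2) & pow2(F3) & pow2(F4),
    doublings = (F2 == 2L * F1) + (F3 == 2L * F2) + (F4 == 2L * F3),
    width = F1 + F2 + F3 + F4
  )
  sols <- dplyr::arrange(
    sols,
    dplyr::desc(monotone), dplyr::desc(all_pow2), candidate_kernel,
    dplyr::desc(width), dplyr::desc(doublings))
  dplyr::mutate(sols, preferred = dplyr::row_number() == 1L)
}

#' The calibrated default architecture
#'
#' The preferred solution of [calibrate_architecture()] at the published
#' parameter total: filters 8/16/32/32, candidate kernel 3, attention key
#' dimension 26, hidden width 32.
#'
#' @param C electrode channels.
#' @return list with `backbone_cfg`, `candidate_kernel`, `attention_dim`.
#' @export
default_architecture <- function(C = 22L) {
  list(backbone_cfg = backbone_config(C = C, F1 = 8L, F2 = 16L, F3 = 32L,
                                      F4 = 32L),
       candidate_kernel = 3L, attention_dim = 26L)
}
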