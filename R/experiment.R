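# Desk-scale end-to-end experiment on phantoms: generate data, split,
# train adversarially (or Dice-only with delta = 0), and evaluate on the
# held-out split. This is the self-contained analogue of a full benchmark
# run, at sizes a single CPU handles in minutes.

#' Run the desk-scale phantom experiment
#'
#' Generates `n` phantom pairs, splits them 70/15/15, trains the adversarial
#' model and evaluates hard-thresholded predictions on the held-out test
#' split.
#'
#' @param seed seed controlling phantoms, initialisation and shuffling.
#' @param n number of phantom pairs.
#' @param image_size phantom side length (divisible by 8).
#' @param epochs training epochs.
#' @param batch_size training batch size.
#' @param delta adversarial weight; 0 gives the Dice-only ablation.
#' @param lam Dice weight.
#' @param gen_config optional [generator_config()] override.
#' @param disc_config optional [discriminator_config()] override.
#' @param phantom optional [phantom_config()] override (its seed is set from
#'   `seed`).
#' @return list with `history` (train_history), `report` (metric_report on
#'   the test split), `gen`, `disc`, and the splits' sizes.
#' @export
run_phantom_experiment <- function(seed = 1L, n = 200L, image_size = 64L,
                                   epochs = 12L, batch_size = 1L,
                                   delta = 1, lam = 1,
                                   gen_config = NULL, disc_config = NULL,
                                   phantom = NULL) {
  pcfg <- phantom %||% phantom_config(image_size = image_size)
  pcfg$seed <- as.integer(seed)
  ds <- generate_dataset(pcfg, n)
  sp <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = seed)
  set.seed(seed + 1L)   # network initialisation stream
  gen <- build_generator(gen_config %||% generator_config())
  disc <- if (delta > 0) {
    build_discriminator(disc_config %||% discriminator_config())
  } else NULL
  tc <- train_config(epochs = epochs, batch_size = batch_size,
                     loss_weights = loss_weights(lam = lam, delta = delta),
                     seed = seed + 2L)
  history <- train(gen, disc, sp$train, sp$val, tc)
  report <- suppressWarnings(evaluate(gen, sp$test))
  list(history = history, report = report, gen = gen, disc = disc,
       n_train = length(sp$train), n_val = length(sp$val),
       n_test = length(sp$test))
}
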