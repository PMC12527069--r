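# Grey Wolf Optimizer: mixed integer/continuous hyperparameter search
# driven by validation accuracy.

#' Define a hyperparameter search space
#'
#' @param names Unique dimension names.
#' @param lower,upper Per-dimension bounds (lower < upper).
#' @param type Per-dimension type: "integer", "continuous" or "log10"
#'   (continuous on the log10 scale, decoded as `10^x`).
#' @return Object of class `search_space` (a data frame).
#' @export
search_space <- function(names, lower, upper,
                         type = rep("continuous", length(names))) {
  if (anyDuplicated(names)) abort_validation("dimension names must be unique")
  if (any(lower >= upper)) abort_validation("need lower < upper per dimension")
  if (!all(type %in% c("integer", "continuous", "log10")))
    abort_validation("type must be integer, continuous or log10")
  structure(data.frame(name = names, lower = lower, upper = upper,
                       type = type, stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' Default hyperparameter space for the hybrid model
#'
#' Five dimensions: number of filters [8, 320], kernel size [3, 7], stride
#' [2, 8], LSTM units [20, 256] (all integer) and dropout rate
#' [0.001, 0.6] (continuous). With `extended = TRUE` two further
#' dimensions are added: learning rate, log-uniform on [1e-4, 3e-3], and a
#' batch-size selector over {16, 20, 32}.
#'
#' @param extended Add learning-rate and batch-size dimensions.
#' @return A [search_space()].
#' @export
default_search_space <- function(extended = FALSE) {
  sp <- search_space(
    names = c("filters", "kernel_size", "stride", "lstm_units", "dropout"),
    lower = c(8, 3, 2, 20, 0.001),
    upper = c(320, 7, 8, 256, 0.6),
    type = c("integer", "integer", "integer", "integer", "continuous"))
  if (extended) {
    sp2 <- search_space(
      names = c("learning_rate", "batch_choice"),
      lower = c(log10(1e-4), 1), upper = c(log10(3e-3), 3),
      type = c("log10", "integer"))
    sp <- structure(rbind(sp, sp2), class = c("search_space", "data.frame"))
  }
  sp
}

#' Decode a wolf position into named hyperparameters
#'
#' Integer dimensions are clipped to bounds and rounded half-up;
#' continuous dimensions are clipped; log10 dimensions are clipped then
#' exponentiated. The `batch_choice` index decodes to the batch-size set
#' {16, 20, 32}.
#'
#' @param position Numeric coordinate vector.
#' @param space A [search_space()].
#' @return Named list of decoded hyperparameter values.
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == nrow(space))
  out <- vector("list", nrow(space))
  names(out) <- space$name
  for (k in seq_len(nrow(space))) {
    x <- clip(position[k], space$lower[k], space$upper[k])
    out[[k]] <- switch(space$type[k],
      integer = as.integer(clip(floor(x + 0.5), ceiling(space$lower[k]),
                                floor(space$upper[k]))),
      continuous = x,
      log10 = 10^x)
  }
  if (!is.null(out$batch_choice)) {
    out$batch_size <- c(16L, 20L, 32L)[out$batch_choice]
    out$batch_choice <- NULL
  }
  out
}

#' One position update driven by the three leaders
#'
#' For each leader k in (alpha, beta, delta) and each dimension, draws
#' `r1, r2 ~ U(0, 1)`, forms `A = 2 a r1 - a` and `C = 2 r2`, computes
#' `D = |C X_leader - X|` and `X_k = X_leader - A D`, and returns the
#' coordinate-wise mean of the three candidate positions clipped to the
#' bounds.
#'
#' @param position Current coordinates.
#' @param alpha,beta,delta Leader coordinate vectors.
#' @param a Control scalar in [0, 2].
#' @param lower,upper Bounds.
#' @param r1,r2 Optional 3 x d matrices of uniform draws (row = leader);
#'   drawn from the ambient RNG when NULL.
#' @return Updated, clipped coordinate vector.
#' @export
update_position <- function(position, alpha, beta, delta, a, lower, upper,
                            r1 = NULL, r2 = NULL) {
  if (a < 0 || a > 2) abort_validation("a must lie in [0, 2]")
  d <- length(position)
  leaders <- rbind(alpha, beta, delta)
  if (is.null(r1)) r1 <- matrix(stats::runif(3 * d), 3, d)
  if (is.null(r2)) r2 <- matrix(stats::runif(3 * d), 3, d)
  A <- 2 * a * r1 - a
  C <- 2 * r2
  X <- matrix(position, 3, d, byrow = TRUE)
  D <- abs(C * leaders - X)
  cand <- leaders - A * D
  clip(colMeans(cand), lower, upper)
}

#' Grey Wolf Optimization
#'
#' Initializes `n_wolves` positions uniformly within bounds, evaluates the
#' fitness of each, ranks the three best as alpha/beta/delta (stable index
#' tie-breaking), and iterates [update_position()] for all wolves with the
#' linear control schedule `a(t) = 2 (1 - t / n_iters)`. Fitness values of
#' repeated decoded positions are cached, and a fitness function that
#' throws sets that wolf's fitness to `-Inf` instead of aborting the
#' search. The best-so-far position is tracked with elitism (its fitness
#' is non-decreasing over iterations).
#'
#' @param fitness_fn Function(decoded hyperparameter list) -> scalar
#'   fitness (larger is better).
#' @param space A [search_space()].
#' @param n_wolves Population size (>= 3).
#' @param n_iters Number of iterations (>= 1).
#' @param seed Integer seed.
#' @return List with `best_position` (coordinates), `best_params`
#'   (decoded), `best_fitness`, `history` (data frame iteration /
#'   best_so_far) and `evaluations` (data frame of every evaluation).
#' @export
gwo_optimize <- function(fitness_fn, space, n_wolves = 10L, n_iters = 20L,
                         seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (!is_count(n_wolves, min = 3))
    abort_validation("n_wolves must be >= 3 (alpha, beta, delta)")
  if (!is_count(n_iters)) abort_validation("n_iters must be >= 1")
  d <- nrow(space)
  cache <- new.env(parent = emptyenv())
  eval_log <- list()
  evaluate <- function(position, iteration) {
    params <- decode_position(position, space)
    key <- paste(vapply(params, format, character(1), digits = 12),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- tryCatch(fitness_fn(params), error = function(e) {
      log_msg("fitness evaluation failed: ", conditionMessage(e),
              level = "WARN")
      -Inf
    })
    if (!is.numeric(fit) || length(fit) != 1 || is.na(fit)) fit <- -Inf
    cache[[key]] <- fit
    eval_log[[length(eval_log) + 1L]] <<- c(list(iteration = iteration),
                                            params, list(fitness = fit))
    fit
  }
  with_seed(seed, {
    pos <- sapply(seq_len(d), function(k) {
      stats::runif(n_wolves, space$lower[k], space$upper[k])
    })
    pos <- matrix(pos, n_wolves, d)
    fit <- vapply(seq_len(n_wolves), function(i) evaluate(pos[i, ], 0L),
                  numeric(1))
    rank3 <- function(f) order(-f, seq_along(f))[1:3]
    lead <- rank3(fit)
    best_fit <- fit[lead[1]]
    best_pos <- pos[lead[1], ]
    history <- data.frame(iteration = integer(0), a = numeric(0),
                          best_so_far = numeric(0))
    for (t in seq_len(n_iters)) {
      a <- gwo_schedule(t, n_iters)
      for (i in seq_len(n_wolves)) {
        pos[i, ] <- update_position(pos[i, ], pos[lead[1], ],
                                    pos[lead[2], ], pos[lead[3], ],
                                    a, space$lower, space$upper)
      }
      fit <- vapply(seq_len(n_wolves), function(i) evaluate(pos[i, ], t),
                    numeric(1))
      lead <- rank3(fit)
      if (fit[lead[1]] > best_fit) {
        best_fit <- fit[lead[1]]
        best_pos <- pos[lead[1], ]
      }
      history <- rbind(history, data.frame(iteration = t, a = a,
                                           best_so_far = best_fit))
    }
    list(best_position = best_pos,
         best_params = decode_position(best_pos, space),
         best_fitness = best_fit,
         history = history,
         evaluations = do.call(rbind, lapply(eval_log, function(e)
           as.data.frame(e, stringsAsFactors = FALSE))))
  })
}

#' Linear control schedule of the encircling coefficient
#'
#' `a(t) = 2 (1 - t / n_iters)`: 2 at t = 0 (exploration), 0 at
#' t = n_iters (pure exploitation).
#'
#' @param t Iteration (0..n_iters).
#' @param n_iters Total iterations.
#' @return The scalar a.
#' @export
gwo_schedule <- function(t, n_iters) 2 * (1 - t / n_iters)

#' Validation-accuracy fitness for hybrid hyperparameters
#'
#' Builds a hybrid model from decoded hyperparameters (conv block 1 gets
#' the searched filter count, block 2 half of it; kernel size, stride and
#' dropout are shared across blocks), trains it under the reduced budget
#' and returns overall validation accuracy. An infeasible architecture
#' (e.g. the feature map collapsing to zero length) scores 0 rather than
#' aborting the search.
#'
#' @param hparams Named list from [decode_position()]: `filters`,
#'   `kernel_size`, `stride`, `lstm_units`, `dropout`, optionally
#'   `learning_rate` and `batch_size`.
#' @param train,valid [beat_dataset()]s.
#' @param budget A [train_config()] giving the per-candidate training
#'   budget (epochs, default learning rate / batch size, seed).
#' @return Fitness in [0, 1].
#' @export
accuracy_fitness <- function(hparams, train, valid,
                             budget = train_config(epochs = 5L,
                                                   optimizer_name = "adamw",
                                                   learning_rate = 1e-3)) {
  cfg_or_err <- tryCatch({
    cfg <- hybrid_params_to_config(hparams, input_len = ncol(train$segments))
    build_hybrid(cfg)
  }, ecgwolf_config_error = function(e) e, ecgwolf_validation_error =
    function(e) e)
  if (inherits(cfg_or_err, "error")) {
    log_msg("infeasible architecture scored 0: ",
            conditionMessage(cfg_or_err), level = "WARN")
    return(0)
  }
  model <- kaiming_init(cfg_or_err, seed = budget$seed)
  cfg <- budget
  if (!is.null(hparams$learning_rate))
    cfg$learning_rate <- hparams$learning_rate
  if (!is.null(hparams$batch_size)) cfg$batch_size <- hparams$batch_size
  fit <- train_model(model, train, valid, cfg)
  ev <- fit$history$valid_acc[nrow(fit$history)]
  if (is.na(ev)) 0 else ev
}

# decoded GWO hyperparameters -> hybrid_config
hybrid_params_to_config <- function(hparams, input_len = 280L) {
  hybrid_config(
    filters = c(hparams$filters, max(8L, as.integer(round(hparams$filters / 2)))),
    kernel_sizes = rep(hparams$kernel_size, 2),
    strides = rep(hparams$stride, 2),
    paddings = c(1L, 1L),
    dropout_rates = rep(hparams$dropout, 2),
    lstm_hidden = hparams$lstm_units,
    input_len = input_len)
}
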