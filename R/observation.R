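#' Task configuration defaults
#'
#' The experimental constants shared by the three tasks: outcomes are won
#' with probability 0.7 in the rating and choice tasks; ratings live on a
#' 0-10 scale; forces are expressed in percent of the subject's maximal
#' grip, with a 10% floor enforced during the task; the effort cost is
#' quadratic in force with scale `effort_cost`.
#'
#' @param win_probability Probability of winning the outcome (rating/choice).
#' @param rating_bounds Length-2 numeric, rating scale bounds.
#' @param force_bounds Length-2 numeric, force bounds in percent of maximum.
#' @param effort_cost Quadratic effort-cost scale (utility per squared unit
#'   of normalized force), must be positive.
#' @return A list of class `task_config`.
#' @export
task_config <- function(win_probability = 0.7,
                        rating_bounds = c(0, 10),
                        force_bounds = c(10, 100),
                        effort_cost = 0.5) {
  stopifnot(win_probability > 0, win_probability <= 1,
            rating_bounds[1] < rating_bounds[2],
            force_bounds[1] < force_bounds[2],
            effort_cost > 0)
  structure(list(win_probability = win_probability,
                 rating_bounds = rating_bounds,
                 force_bounds = force_bounds,
                 effort_cost = effort_cost),
            class = "task_config")
}

#' Softmax probability of choosing the left option
#'
#' `p = 1 / (1 + exp(-(V_L - V_R) / temperature))`. Larger temperatures give
#' more stochastic choices; the two option probabilities sum to one exactly.
#' Numerically stable for value differences up to ~1e3 temperatures.
#'
#' @param value_left,value_right Utilities of the two options (vectors,
#'   recycled).
#' @param temperature Positive softmax temperature.
#' @return Probability of choosing the left option, in (0, 1).
#' @examples
#' choice_probability(10, 10, 2)            # 0.5
#' choice_probability(log(3), 0, 1)         # 0.75
#' @export
choice_probability <- function(value_left, value_right, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be > 0")
  stats::plogis((value_left - value_right) / temperature)
}

#' Net utility of a response in each task
#'
#' The task-specific objective an ideal responder maximizes: in the choice
#' task the win-probability-weighted difference between chosen and unchosen
#' values (the unchosen option is an opportunity cost); in the rating task
#' the negative squared error between the overt rating and the covert value;
#' in the force task the expected value (value times the force, which sets
#' the win probability) minus a quadratic effort cost.
#'
#' @param task One of `"choice"`, `"rating"`, `"force"`.
#' @param value_chosen,value_unchosen Chosen/unchosen values (choice task).
#' @param rating Overt rating (rating task).
#' @param value Covert outcome value (rating and force tasks).
#' @param force Force as a fraction of maximum in \[0, 1\] (force task).
#' @param effort_cost Quadratic effort-cost scale (force task).
#' @param win_probability Outcome probability in the choice task.
#' @return Net utility (scalar or vector).
#' @export
net_utility <- function(task, value_chosen = NULL, value_unchosen = NULL,
                        rating = NULL, value = NULL, force = NULL,
                        effort_cost = NULL, win_probability = 0.7) {
  switch(match.arg(task, c("choice", "rating", "force")),
         choice = win_probability * (value_chosen - value_unchosen),
         rating = -(rating - value)^2,
         force  = value * force - effort_cost * force^2)
}

#' Optimal response under the net-utility model
#'
#' The rating maximizing `-(R - V)^2` is the value itself; the force
#' maximizing `V * F - effort_cost * F^2` is `V / (2 * effort_cost)`. Both
#' are linear in value, which justifies the linear scaling used by the
#' observation model.
#'
#' @param task `"rating"` or `"force"`.
#' @param value Outcome value(s).
#' @param effort_cost Positive effort-cost scale (force task).
#' @return Optimal response on the same scale as `value` (rating) or as a
#'   fraction of maximal force (force).
#' @export
optimal_response <- function(task, value, effort_cost = NULL) {
  switch(match.arg(task, c("rating", "force")),
         rating = value,
         force = {
           if (is.null(effort_cost) || any(effort_cost <= 0))
             stop("effort_cost must be > 0 for the force task")
           value / (2 * effort_cost)
         })
}

#' Linearly scaled response, clipped to task bounds
#'
#' Ratings and forces are modelled as `a * V + b` clipped to the response
#' scale.
#'
#' @param value Utilities.
#' @param slope,intercept Scaling parameters (response units per utility
#'   unit; response units).
#' @param bounds Length-2 numeric response bounds.
#' @return Expected response, clipped.
#' @export
expected_scaled_response <- function(value, slope, intercept, bounds) {
  pmin(pmax(slope * value + intercept, bounds[1]), bounds[2])
}
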