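#' Generative observers for the trial simulator
#'
#' An observer fixes the true sensitivity d' and criterion c for every
#' (task, distance) combination the simulator can present.
#'
#' `observer_categorical()` specifies d' freely per task and distance (the
#' generative counterpart of the categorical-distance model): a vector of d'
#' over the distance grid per task, plus one c per task (a per-distance c
#' vector is also accepted).
#'
#' `observer_exponential()` specifies d' as an exponential function of
#' distance, `d'(x) = amplitude * exp(rate * x)`, with one (amplitude, rate)
#' pair per task and one criterion per task — the generative counterpart of
#' the exponential-distance model. The amplitude is the d' extrapolated to
#' distance 0; a negative rate gives the empirically typical decay of
#' sensitivity with reflector distance.
#'
#' @param distances_m Distance grid the categorical observer is defined on.
#' @param d_prime_detection,d_prime_localization d' per distance (length 1 is
#'   recycled over the grid).
#' @param c_detection,c_localization Criterion per task (length 1, or one per
#'   distance for the categorical observer).
#' @param alpha0,alpha1 Detection-task amplitude and rate (per meter).
#' @param beta0,beta1 Localization-task amplitude and rate.
#' @param c0,c1 Detection and localization criteria (distance-constant).
#' @return An object of class `echo_observer`.
#' @examples
#' observer_exponential(3, -0.4, 2, -0.6, 0.1, -0.2)
#' observer_categorical(d_prime_detection = 2, d_prime_localization = 1)
#' @name echo_observer
NULL

#' @rdname echo_observer
#' @export
observer_categorical <- function(distances_m = c(1.00, 1.36, 1.72, 2.08, 2.44,
                                                 2.81, 3.17, 3.53, 3.89, 4.25),
                                 d_prime_detection = 0,
                                 d_prime_localization = 0,
                                 c_detection = 0,
                                 c_localization = 0) {
  k <- length(distances_m)
  expand <- function(v, what, allow_per_distance = TRUE) {
    if (length(v) == 1) v <- rep(v, k)
    if (length(v) != k) {
      stop("`", what, "` must have length 1 or length(distances_m)",
           call. = FALSE)
    }
    if (any(!is.finite(v))) stop("`", what, "` must be finite", call. = FALSE)
    as.numeric(v)
  }
  structure(
    list(
      form = "categorical",
      distances_m = as.numeric(distances_m),
      d_prime = list(detection = expand(d_prime_detection, "d_prime_detection"),
                     localization = expand(d_prime_localization,
                                           "d_prime_localization")),
      criterion = list(detection = expand(c_detection, "c_detection"),
                       localization = expand(c_localization, "c_localization"))
    ),
    class = c("echo_observer_categorical", "echo_observer")
  )
}

#' @rdname echo_observer
#' @export
observer_exponential <- function(alpha0, alpha1, beta0, beta1, c0 = 0, c1 = 0) {
  pars <- c(alpha0 = alpha0, alpha1 = alpha1, beta0 = beta0, beta1 = beta1,
            c0 = c0, c1 = c1)
  if (any(!is.finite(pars))) stop("observer parameters must be finite",
                                  call. = FALSE)
  structure(list(form = "exponential", params = pars),
            class = c("echo_observer_exponential", "echo_observer"))
}

#' True sensitivity of an observer
#'
#' @param observer An `echo_observer`.
#' @param task Character vector of task labels.
#' @param distance_m Numeric vector of distances (recycled with `task`).
#' @return Numeric vector of true d' values.
#' @export
observer_dprime <- function(observer, task, distance_m) {
  UseMethod("observer_dprime")
}

#' @export
observer_dprime.echo_observer_categorical <- function(observer, task,
                                                      distance_m) {
  idx <- match(distance_m, observer$distances_m)
  if (anyNA(idx)) {
    stop("distance(s) not on the categorical observer's grid: ",
         paste(unique(distance_m[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  loc <- task == "localization"
  out <- observer$d_prime$detection[idx]
  out[loc] <- observer$d_prime$localization[idx[loc]]
  out
}

#' @export
observer_dprime.echo_observer_exponential <- function(observer, task,
                                                      distance_m) {
  p <- observer$params
  ifelse(task == "localization",
         p[["beta0"]] * exp(p[["beta1"]] * distance_m),
         p[["alpha0"]] * exp(p[["alpha1"]] * distance_m))
}

#' True criterion of an observer
#'
#' @inheritParams observer_dprime
#' @param distance_m Distances; only used by categorical observers with
#'   per-distance criteria.
#' @return Numeric vector of true c values.
#' @export
observer_criterion <- function(observer, task, distance_m = NULL) {
  UseMethod("observer_criterion")
}

#' @export
observer_criterion.echo_observer_categorical <- function(observer, task,
                                                         distance_m = NULL) {
  if (is.null(distance_m)) {
    # distance-constant lookup: valid because constructors recycle scalars
    ifelse(task == "localization",
           observer$criterion$localization[1],
           observer$criterion$detection[1])
  } else {
    idx <- match(distance_m, observer$distances_m)
    loc <- task == "localization"
    out <- observer$criterion$detection[idx]
    out[loc] <- observer$criterion$localization[idx[loc]]
    out
  }
}

#' @export
observer_criterion.echo_observer_exponential <- function(observer, task,
                                                         distance_m = NULL) {
  p <- observer$params
  ifelse(task == "localization", p[["c1"]], p[["c0"]])
}

#' @export
print.echo_observer <- function(x, ...) {
  if (x$form == "exponential") {
    cat("<echo_observer: exponential d'(x) = a * exp(r x)>\n")
    print(round(x$params, 4))
  } else {
    cat("<echo_observer: categorical over",
        length(x$distances_m), "distances>\n")
    print(tibble::tibble(
      distance_m = x$distances_m,
      dprime_detection = x$d_prime$detection,
      dprime_localization = x$d_prime$localization,
      c_detection = x$criterion$detection,
      c_localization = x$criterion$localization))
  }
  invisible(x)
}
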