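# Conditional-mean learners shared by the treatment- and outcome-model
# fitters. Each learner is fitted on a numeric design matrix (binary or
# numeric columns, no intercept column) and predicts a conditional mean for
# new rows. Supported:
#   "saturated"  exact cell means over the distinct rows of the design
#                (nonparametric MLE on a discrete history space)
#   "logistic"   main-terms logistic regression (quasibinomial, so pseudo
#                outcomes in [0,1] are accepted)
#   "linear"     main-terms ordinary least squares
#   "intercept"  overall mean, ignoring the design (used to study
#                misspecification and double robustness)
#   a function   plugin learner: function(y, X, newX) -> predictions

fit_mean_learner <- function(y, X, learner) {
  if (is.function(learner)) {
    return(structure(list(y = y, X = X, fun = learner),
                     class = c("plugin_learner", "mean_learner")))
  }
  learner <- match.arg(learner, c("saturated", "logistic", "linear",
                                  "intercept"))
  if (nrow(X) == 0 || length(y) == 0) abort("empty fitting subset")
  fit <- switch(learner,
    saturated = {
      key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
      means <- tapply(y, key, mean)
      list(means = means)
    },
    logistic = {
      Xd <- cbind(`(Intercept)` = 1, drop_constant_cols(X))
      g <- suppressWarnings(
        glm.fit(Xd, y, family = quasibinomial(), control = list(maxit = 100))
      )
      list(coef = g$coefficients, cols = colnames(Xd))
    },
    linear = {
      Xd <- cbind(`(Intercept)` = 1, drop_constant_cols(X))
      qrX <- qr(Xd)
      beta <- qr.coef(qrX, y)
      beta[is.na(beta)] <- 0
      list(coef = beta, cols = colnames(Xd))
    },
    intercept = list(mean = mean(y))
  )
  structure(c(fit, list(type = learner, n = length(y))),
            class = c(paste0(learner, "_learner"), "mean_learner"))
}

predict_mean_learner <- function(object, newX) {
  if (inherits(object, "plugin_learner")) {
    return(as.numeric(object$fun(object$y, object$X, newX)))
  }
  switch(object$type,
    saturated = {
      key <- do.call(paste, c(as.data.frame(newX), sep = "\r"))
      p <- unname(object$means[key])
      if (anyNA(p)) {
        abort(paste0("saturated learner asked to predict in an empty cell ",
                     "(history never observed in the fitting subset); ",
                     "positivity violation"))
      }
      as.numeric(p)
    },
    logistic = {
      Xd <- cbind(`(Intercept)` = 1, newX)[, object$cols, drop = FALSE]
      eta <- drop(Xd %*% object$coef)
      plogis(eta)
    },
    linear = {
      Xd <- cbind(`(Intercept)` = 1, newX)[, object$cols, drop = FALSE]
      drop(Xd %*% object$coef)
    },
    intercept = rep(object$mean, nrow(newX))
  )
}

# glm.fit chokes on constant columns only via aliasing; drop them so the
# coefficient vector stays well defined and predictions line up by name
drop_constant_cols <- function(X) {
  if (ncol(X) == 0) return(X)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  X[, keep, drop = FALSE]
}

check_learner <- function(learner) {
  if (is.function(learner)) return(invisible(learner))
  if (!is.character(learner) || length(learner) != 1 ||
      !learner %in% c("saturated", "logistic", "linear", "intercept")) {
    abort(paste0("learner must be one of \"saturated\", \"logistic\", ",
                 "\"linear\", \"intercept\", or a plugin function"))
  }
  invisible(learner)
}
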