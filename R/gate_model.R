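#' Train the two-stage supervised gating model
#'
#' Mirrors the two-step automaton architecture: a first, instrument-
#' specific stage classifies events into scatter-level classes from
#' forward/side scatter (scatter signals differ strongly between
#' cytometers, so one scatter model per instrument), and a second,
#' instrument-agnostic stage assigns the marker-level populations within
#' each scatter class from the fluorescence channels (pooled across
#' instruments, since marker space is on the shared normalized scale).
#'
#' The classifier family is a configuration choice; the default is a
#' classification tree (`rpart`, deterministic given the data), with
#' linear discriminant analysis (`MASS::lda`) as the alternative.
#'
#' @param training list of training samples, each a list with `em` (an
#'   [event_matrix()], instrument read from its metadata) and `labels`
#'   (factor from [gate_events()] or generator ground truth). At least
#'   one labeled sample per instrument is required.
#' @param defs the population definitions (supplies the tree structure).
#' @param engine `"rpart"` or `"lda"`.
#' @return a `gate_model` with per-instrument stage-1 models and shared
#'   per-scatter-class stage-2 models.
#' @export
train_gate_model <- function(training, defs, engine = c("rpart", "lda")) {
  engine <- match.arg(engine)
  stopifnot(length(training) >= 1L)
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  level1 <- names(defs)[vapply(defs, `[[`, character(1), "parent") == "all"]
  frames <- lapply(training, function(tr) {
    em <- tr$em
    lab <- as.character(tr$labels)
    stopifnot(length(lab) == n_events(em))
    ulab <- unique(lab)
    map <- vapply(ulab, scatter_class, character(1),
                  defs = defs, level1 = level1)
    sc <- unname(map[lab])
    fluo <- fluorescence_channels(em)
    df <- as.data.frame(log_features(em$values[, c("FSC", "SSC", fluo), drop = FALSE]))
    df$.scatter_class <- sc
    df$.label <- lab
    df$.instrument <- em$meta$instrument_id
    df
  })
  all_df <- do.call(rbind, frames)
  fluo <- setdiff(names(all_df), c("FSC", "SSC", ".scatter_class", ".label",
                                   ".instrument"))
  stage1 <- lapply(split(all_df, all_df$.instrument), function(d) {
    fit_classifier(d[, c("FSC", "SSC")], d$.scatter_class, engine)
  })
  stage2 <- list()
  for (cls in unique(all_df$.scatter_class)) {
    d <- all_df[all_df$.scatter_class == cls, ]
    if (length(unique(d$.label)) < 2L) next  # leaf class, nothing to learn
    stage2[[cls]] <- fit_classifier(d[, fluo, drop = FALSE], d$.label, engine)
  }
  structure(list(stage1 = stage1, stage2 = stage2, engine = engine,
                 level1 = level1, fluo = fluo,
                 label_levels = c("all", names(defs))),
            class = "gate_model")
}

# depth-1 (scatter-level) ancestor of a deepest label
scatter_class <- function(label, defs, level1) {
  if (label %in% c("all", level1)) return(label)
  cur <- label
  while (!is.null(defs[[cur]]) && !defs[[cur]]$parent %in% c("all")) {
    cur <- defs[[cur]]$parent
  }
  cur
}

log_features <- function(m) log10(pmax(m, 1))

fit_classifier <- function(x, y, engine) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    return(structure(list(constant = as.character(levels(y)[1L])),
                     class = "constant_classifier"))
  }
  d <- cbind(x, .y = y)
  if (engine == "rpart") {
    rpart::rpart(.y ~ ., data = d, method = "class",
                 control = rpart::rpart.control(cp = 1e-3, minsplit = 10L,
                                                minbucket = 5L, xval = 0L))
  } else {
    MASS::lda(.y ~ ., data = d)
  }
}

predict_classifier <- function(model, x) {
  if (inherits(model, "constant_classifier")) {
    return(rep(model$constant, nrow(x)))
  }
  if (inherits(model, "rpart")) {
    as.character(predict(model, newdata = x, type = "class"))
  } else {
    as.character(predict(model, newdata = x)$class)
  }
}

#' Predict population labels with a trained gate model
#'
#' Stage 1 (per-instrument scatter model) assigns scatter classes, then
#' stage 2 (shared marker model) assigns the final population within
#' each class; labels respect the population tree by construction. For
#' an instrument unseen at training time the model falls back to
#' threshold gating with a warning when `defs`/`thresholds` are
#' supplied, and errors otherwise.
#'
#' @param em an [event_matrix()].
#' @param model a [train_gate_model()] fit.
#' @param defs,thresholds fallback threshold-gating configuration for
#'   unseen instruments (optional).
#' @return factor of labels, same levels as [gate_events()].
#' @export
predict_gates <- function(em, model, defs = NULL, thresholds = NULL) {
  stopifnot(inherits(em, "event_matrix"), inherits(model, "gate_model"))
  instr <- em$meta$instrument_id
  if (is.na(instr) || !instr %in% names(model$stage1)) {
    if (!is.null(defs) && !is.null(thresholds)) {
      warning(sprintf("instrument '%s' unseen at training time; falling back to threshold gating", instr))
      return(gate_events(em, defs, thresholds))
    }
    stop(sprintf("instrument '%s' unseen at training time and no threshold fallback supplied", instr))
  }
  missing_ch <- setdiff(c("FSC", "SSC", model$fluo), em$channels)
  if (length(missing_ch)) {
    stop(sprintf("prediction requires channel(s) missing from data: %s",
                 paste(missing_ch, collapse = ", ")))
  }
  feats <- as.data.frame(log_features(em$values[, c("FSC", "SSC", model$fluo),
                                                drop = FALSE]))
  cls <- predict_classifier(model$stage1[[instr]], feats[, c("FSC", "SSC")])
  labels <- cls
  for (c2 in names(model$stage2)) {
    idx <- which(cls == c2)
    if (!length(idx)) next
    labels[idx] <- predict_classifier(model$stage2[[c2]],
                                      feats[idx, model$fluo, drop = FALSE])
  }
  factor(labels, levels = model$label_levels)
}
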