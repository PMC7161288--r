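# The stepwise item-analysis procedure: fit the Partial Credit model, test
# overall fit and global DIF, inspect conditional item fit, screen all
# candidate LD pairs and DIF terms with Kelderman LR tests under BH
# correction, extend the model one term at a time, and exclude an item only
# when no admissible term explains its misfit; iterate to a final measurement
# model, then derive reliability, targeting, conversion tables and
# dimensionality.

#' Analysis configuration for the stepwise pipeline
#'
#' @param alpha significance level for all decisions (default 0.05).
#' @param max_exclusions maximum items removed per scale before the pipeline
#'   reports that no admissible model exists.
#' @param max_terms maximum LD/DIF terms added per scale.
#' @param max_term_trials when an item misfits, how many of the strongest
#'   BH-surviving candidate terms involving it are tried before the item is
#'   excluded.
#' @param item_fit_B parametric bootstrap replicates for item fit.
#' @param min_items smallest admissible scale.
#' @param seed integer seed fixed at the start of each scale analysis, making
#'   pipeline decisions a pure function of (data, config, seed).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, max_exclusions = 4L, max_terms = 12L,
                            max_term_trials = 5L, item_fit_B = 200L,
                            min_items = 3L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, max_exclusions = max_exclusions,
                 max_terms = max_terms, max_term_trials = max_term_trials,
                 item_fit_B = item_fit_B, min_items = min_items, seed = seed),
            class = "analysis_config")
}

# all admissible candidate terms for the current model
candidate_terms <- function(model, covariates) {
  items <- model$items
  in_pair <- unlist(model$ld)
  cands <- list()
  free_items <- setdiff(items, in_pair)
  if (length(free_items) >= 2L) {
    cmb <- utils::combn(free_items, 2L)
    for (j in seq_len(ncol(cmb)))
      cands[[length(cands) + 1L]] <- list(items = sort(cmb[, j]))
  }
  have_dif <- vapply(model$dif, function(d) paste(d$item, d$covariate), "")
  for (it in items) for (cv in covariates) {
    if (paste(it, cv) %in% have_dif) next
    cands[[length(cands) + 1L]] <- list(item = it, covariate = cv)
  }
  cands
}

screen_candidates <- function(data, model, covariates) {
  cands <- candidate_terms(model, covariates)
  if (!length(cands)) return(NULL)
  rows <- lapply(cands, function(cd) {
    kt <- kelderman_lr(data, model, cd)
    kt$term <- term_key(if (!is.null(cd$items)) list(items = cd$items) else cd)
    kt
  })
  out <- do.call(rbind, rows)
  out$candidate <- cands
  out$p_adj <- bh_adjust(out$p_value)
  out[order(out$p_adj, out$p_value), ]
}

# partial-gamma effect size for a candidate term (tie-breaking, reporting)
candidate_gamma <- function(data, model, cd) {
  g <- tryCatch({
    if (!is.null(cd$items))
      partial_gamma_ld(data, cd$items[1], cd$items[2], model$items)$gamma_avg
    else
      partial_gamma_dif(data, cd$item, cd$covariate, model$items)$gamma
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  g
}

#' Stepwise item analysis of one scale
#'
#' Runs the full decision loop on one item set: (1) fit the current model by
#' CML; (2) compute conditional item fit; (3) Kelderman-screen every
#' admissible LD pair and item-by-covariate DIF term, BH-adjusting the
#' screening family of the iteration (item-fit p-values are BH-adjusted over
#' the item family the same way); (4) if an item shows significant
#' misfit, try the strongest surviving candidate terms involving it and keep
#' the first that renders the item's fit acceptable -- if none does, exclude
#' the item and restart with an empty term set; (5) otherwise add the single
#' most significant surviving term (ties broken by the larger absolute
#' partial gamma); (6) stop when nothing survives screening, no item
#' misfits, and the homogeneity and global-DIF CLR tests are all
#' non-significant.
#'
#' @param data a [response_data()].
#' @param items the scale's items.
#' @param covariates covariate names screened for DIF.
#' @param config an [analysis_config()].
#' @param scale_name label used in the log.
#' @return list with elements `model` (final fit or `NULL` if no admissible
#'   model), `admissible` (logical), `log` (decision data frame), `item_fit`,
#'   `clr` (final CLR table), `screening` (final screening table),
#'   `excluded`, `items`.
#' @export
stepwise_scale_analysis <- function(data, items, covariates = character(),
                                    config = analysis_config(),
                                    scale_name = "scale") {
  set.seed(config$seed)
  log_rows <- list()
  note <- function(action, detail, stat = NA_real_, p = NA_real_)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      scale = scale_name, step = length(log_rows) + 1L, action = action,
      detail = detail, statistic = stat, p_value = p, stringsAsFactors = FALSE)
  cur_items <- items
  ld <- list(); dif <- list()
  excluded <- character()
  model <- NULL
  fit_ctrl <- list(gtol = 1e-4)   # screening fits; the final fit is polished
  # percentile bootstrap p-values are bounded below by 2/(B+1); make sure the
  # BH-adjusted minimum can still fall under alpha for the item family
  B_fit <- max(config$item_fit_B,
               ceiling(2 * length(items) / config$alpha) + 1L)
  repeat {
    model <- gllrm_fit(data, cur_items, ld = ld, dif = dif, start = model,
                       se = FALSE, control = fit_ctrl)
    itf <- conditional_item_fit(data, model, B = B_fit)
    itf$infit_p_adj <- bh_adjust(itf$infit_p)
    scr <- screen_candidates(data, model, covariates)
    misfit <- itf[which(itf$infit_p_adj < config$alpha), , drop = FALSE]
    if (nrow(misfit)) {
      worst <- misfit$item[which.max(abs(misfit$infit - 1))]
      worst_infit <- misfit$infit[misfit$item == worst]
      note("item_misfit", worst, worst_infit,
           itf$infit_p[itf$item == worst])
      # try the strongest surviving candidate terms: first those involving
      # the misfitting item, then the strongest overall -- apparent misfit of
      # one item is often spillover from an unmodelled term elsewhere,
      # because fit statistics are relative to the whole item set
      fixed <- FALSE
      if (!is.null(scr)) {
        involves <- vapply(scr$candidate, function(cd)
          worst %in% c(cd$items, cd$item), TRUE)
        surviving <- scr$p_adj < config$alpha & !is.na(scr$p_adj)
        trials <- c(which(involves & surviving), which(!involves & surviving))
        trials <- head(trials, config$max_term_trials)
        for (tr in trials) {
          cd <- scr$candidate[[tr]]
          ld2 <- ld; dif2 <- dif
          if (!is.null(cd$items)) ld2 <- c(ld2, list(cd$items))
          else dif2 <- c(dif2, list(cd))
          m2 <- tryCatch(gllrm_fit(data, cur_items, ld = ld2, dif = dif2,
                                   start = model, se = FALSE,
                                   control = fit_ctrl),
                         error = function(e) NULL)
          if (is.null(m2)) next
          itf2 <- conditional_item_fit(data, m2, B = B_fit)
          itf2$infit_p_adj <- bh_adjust(itf2$infit_p)
          p_worst <- itf2$infit_p_adj[match(worst, itf2$item)]
          ok_full <- !is.na(p_worst) && p_worst >= config$alpha
          if (ok_full) {
            ld <- ld2; dif <- dif2; model <- m2
            note("term_added_for_misfit", paste0(scr$term[tr], " -> ", worst),
                 scr$statistic[tr], scr$p_adj[tr])
            fixed <- TRUE
            break
          }
        }
      }
      if (fixed) next
      # no admissible term explains the misfit: exclude an item and restart.
      # Under-discrimination is the signature of an item that measures the
      # construct poorly, so the exclusion target is the worst significantly
      # under-discriminating item when one exists (over-discrimination
      # usually reflects LD that later terms will absorb); otherwise the
      # focal item itself is removed.
      if (length(excluded) >= config$max_exclusions ||
          length(cur_items) - 1L < config$min_items) {
        note("no_admissible_model", "exclusion budget exhausted")
        return(list(model = NULL, admissible = FALSE,
                    log = do.call(rbind, log_rows), item_fit = itf,
                    clr = NULL, screening = scr, excluded = excluded,
                    items = cur_items))
      }
      over1 <- misfit$infit > 1
      drop_item <- if (any(over1))
        misfit$item[over1][which.max(misfit$infit[over1])] else worst
      excluded <- c(excluded, drop_item)
      cur_items <- setdiff(cur_items, drop_item)
      ld <- list(); dif <- list(); model <- NULL
      note("item_excluded", drop_item)
      next
    }
    if (!is.null(scr) && any(scr$p_adj < config$alpha, na.rm = TRUE)) {
      if (length(ld) + length(dif) >= config$max_terms) {
        note("no_admissible_model", "term budget exhausted")
        return(list(model = NULL, admissible = FALSE,
                    log = do.call(rbind, log_rows), item_fit = itf,
                    clr = NULL, screening = scr, excluded = excluded,
                    items = cur_items))
      }
      top <- which(scr$p_adj < config$alpha)
      # tie-break equal adjusted p by the larger absolute partial gamma
      best_p <- min(scr$p_adj[top])
      tied <- top[scr$p_adj[top] <= best_p + 1e-12]
      if (length(tied) > 1L) {
        gs <- vapply(tied, function(ix)
          abs(candidate_gamma(data, model, scr$candidate[[ix]]) %||% 0), 0)
        pick <- tied[which.max(gs)]
      } else pick <- tied[1]
      cd <- scr$candidate[[pick]]
      if (!is.null(cd$items)) ld <- c(ld, list(cd$items))
      else dif <- c(dif, list(cd))
      note("term_added", scr$term[pick], scr$statistic[pick], scr$p_adj[pick])
      next
    }
    # nothing survives screening and no item misfit: check the global tests
    # (homogeneity + one global-DIF CLR per covariate), BH-adjusted as one
    # family like every other multiple-test family in the procedure
    clr_rows <- list(clr_test(data, model, "score"))
    for (cv in covariates)
      clr_rows[[length(clr_rows) + 1L]] <- clr_test(data, model, cv)
    clr <- do.call(rbind, clr_rows)
    clr$p_adj <- bh_adjust(clr$p_value)
    if (all(clr$p_adj >= config$alpha)) {
      note("model_accepted",
           paste0("items: ", paste(cur_items, collapse = ","),
                  if (length(ld)) paste0("; LD: ", paste(vapply(ld, paste, "",
                    collapse = "~"), collapse = ",")) else "",
                  if (length(dif)) paste0("; DIF: ", paste(vapply(dif,
                    function(d) paste0(d$item, "*", d$covariate), ""),
                    collapse = ",")) else ""))
      # final polished fit with standard errors
      model <- gllrm_fit(data, cur_items, ld = ld, dif = dif, start = model)
      return(list(model = model, admissible = TRUE,
                  log = do.call(rbind, log_rows), item_fit = itf, clr = clr,
                  screening = scr, excluded = excluded, items = cur_items))
    }
    # residual global misfit without an item-level signal: remove the item
    # deviating most from expectation (under-discriminating items first)
    worst <- if (any(itf$infit > 1))
      itf$item[itf$infit > 1][which.max(itf$infit[itf$infit > 1])]
    else itf$item[which.max(abs(itf$infit - 1))]
    bad <- clr[clr$p_adj < config$alpha, ][1, ]
    note("global_misfit_exclusion", paste0(worst, " (", bad$grouping, ")"),
         bad$statistic, bad$p_value)
    if (length(excluded) >= config$max_exclusions ||
        length(cur_items) - 1L < config$min_items) {
      note("no_admissible_model", "exclusion budget exhausted")
      return(list(model = NULL, admissible = FALSE,
                  log = do.call(rbind, log_rows), item_fit = itf, clr = clr,
                  screening = scr, excluded = excluded, items = cur_items))
    }
    excluded <- c(excluded, worst)
    cur_items <- setdiff(cur_items, worst)
    ld <- list(); dif <- list(); model <- NULL
  }
}

#' Run the complete item analysis over both subscales
#'
#' Per subscale: the stepwise loop of [stepwise_scale_analysis()]. If both
#' subscales reach an admissible model, the between-subscale
#' unidimensionality test is run on reverse-scored data, and per-scale
#' reliability (Cronbach's alpha and the LD-adjusted Monte Carlo estimate),
#' person separation, targeting, DIF conversion tables and adjusted group
#' comparisons are produced. Criterion validity (Kendall's tau against
#' supplied correlates) is reported when `correlates` are given.
#'
#' @param data a [response_data()].
#' @param specs named list of [scale_spec()]s (typically the two subscales);
#'   the first spec's `reverse_scored` items are reversed for the
#'   dimensionality analysis.
#' @param covariates covariates screened for DIF.
#' @param config an [analysis_config()].
#' @param correlates optional data frame of criterion scores (one column per
#'   measure, one row per person).
#' @param mc_n Monte Carlo size for reliability/separation.
#' @return a list of class `item_analysis` with per-scale results and the
#'   cross-scale analyses.
#' @export
run_item_analysis <- function(data, specs, covariates = character(),
                              config = analysis_config(), correlates = NULL,
                              mc_n = 20000L) {
  scales <- lapply(names(specs), function(nm)
    stepwise_scale_analysis(data, specs[[nm]]$items, covariates, config,
                            scale_name = nm))
  names(scales) <- names(specs)
  out <- list(scales = scales, config = config)
  ok <- vapply(scales, `[[`, TRUE, "admissible")
  if (all(ok) && length(scales) == 2L) {
    rev_spec <- specs[[1]]
    rev_spec$items <- intersect(rev_spec$items, scales[[1]]$items)
    rev_spec$reverse_scored <- intersect(rev_spec$reverse_scored,
                                         scales[[1]]$items)
    data_rev <- apply_reverse_scoring(data, rev_spec)
    model_a_rev <- gllrm_fit(data_rev, scales[[1]]$items,
                             ld = scales[[1]]$model$ld,
                             dif = scales[[1]]$model$dif, se = FALSE)
    set.seed(config$seed + 1L)
    out$dimensionality <- unidimensionality_test(data_rev, model_a_rev,
                                                 scales[[2]]$model)
    out$scale_summaries <- lapply(names(scales), function(nm) {
      sc <- scales[[nm]]
      pd <- fit_person_dist(data, sc$model)
      ti <- target_index(sc$model, pd)
      rel <- mc_reliability(sc$model, pd, n_sim = mc_n,
                            seed = config$seed + 2L)
      sep <- person_separation(sc$model, pd, n_sim = mc_n,
                               seed = config$seed + 3L)
      conv <- if (length(sc$model$dif)) dif_conversion_table(sc$model) else NULL
      adj <- NULL
      if (!is.null(conv)) {
        adj <- lapply(names(sc$model$cov_levels), function(cv)
          adjusted_group_comparison(data, sc$model, conv, cv))
        names(adj) <- names(sc$model$cov_levels)
      }
      list(scale = nm, person_dist = pd, targeting = ti,
           alpha = cronbach_alpha(data, sc$items), reliability = rel,
           separation = sep, conversion = conv, adjusted = adj)
    })
    names(out$scale_summaries) <- names(scales)
    if (!is.null(correlates)) {
      rows <- list()
      for (nm in names(scales)) {
        sc_total <- total_scores(data, scales[[nm]]$items)$score
        for (cr in names(correlates)) {
          kt <- kendall_tau(sc_total, correlates[[cr]])
          rows[[length(rows) + 1L]] <- data.frame(
            scale = nm, correlate = cr, tau = kt$tau, p_value = kt$p_value,
            n = kt$n, stringsAsFactors = FALSE)
        }
      }
      out$criterion_validity <- do.call(rbind, rows)
    }
  }
  class(out) <- "item_analysis"
  out
}

#' Write the analysis report tables
#'
#' Emits the run's artifacts as CSV tables in `dir`: the decision log,
#' model-fit/global-DIF CLR tests, item fit statistics, final screening
#' results, targeting and reliability per subgroup, conversion tables (with
#' the reminder that unadjusted total-score comparisons between subgroups
#' are invalid in the presence of DIF), adjusted group comparisons,
#' dimensionality, and criterion validity. Re-running on an identical result
#' object reproduces the files byte for byte.
#'
#' @param result an `item_analysis` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
render_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  logs <- do.call(rbind, lapply(result$scales, `[[`, "log"))
  emit(logs, "decision_log.csv")
  for (nm in names(result$scales)) {
    sc <- result$scales[[nm]]
    if (!is.null(sc$clr)) emit(sc$clr, paste0("clr_", nm, ".csv"))
    emit(sc$item_fit, paste0("item_fit_", nm, ".csv"))
    if (!is.null(sc$screening))
      emit(sc$screening[setdiff(names(sc$screening), "candidate")],
           paste0("screening_", nm, ".csv"))
    if (!is.null(sc$model)) {
      emit(parameter_table(sc$model), paste0("parameters_", nm, ".csv"))
      edges <- model_edges(sc$model)
      if (!is.null(edges)) emit(edges, paste0("graph_", nm, ".csv"))
    }
  }
  if (!is.null(result$dimensionality))
    emit(result$dimensionality, "dimensionality.csv")
  if (!is.null(result$scale_summaries)) {
    for (nm in names(result$scale_summaries)) {
      ss <- result$scale_summaries[[nm]]
      tg <- ss$targeting
      tg$reliability <- c(ss$reliability$reliability,
                          rep(NA, nrow(tg) - nrow(ss$reliability)))
      tg$separation <- c(ss$separation$separation,
                         rep(NA, nrow(tg) - nrow(ss$separation)))
      tg$cronbach_alpha <- ss$alpha
      emit(tg, paste0("targeting_reliability_", nm, ".csv"))
      if (!is.null(ss$conversion)) {
        conv <- ss$conversion
        conv$note <- "scores adjusted for DIF; unadjusted total-score comparisons between subgroups are invalid"
        emit(conv, paste0("conversion_table_", nm, ".csv"))
        adjrows <- do.call(rbind, lapply(names(ss$adjusted), function(cv)
          cbind(covariate = cv, ss$adjusted[[cv]]$by_group)))
        emit(adjrows, paste0("adjusted_scores_", nm, ".csv"))
      }
    }
  }
  if (!is.null(result$criterion_validity))
    emit(result$criterion_validity, "criterion_validity.csv")
  invisible(files)
}

# LD/DIF edge list of a fitted model with partial-gamma magnitudes
model_edges <- function(model) {
  if (!length(model$ld) && !length(model$dif)) return(NULL)
  rows <- list()
  for (pair in model$ld)
    rows[[length(rows) + 1L]] <- data.frame(
      from = pair[1], to = pair[2], type = "LD", stringsAsFactors = FALSE)
  for (d in model$dif)
    rows[[length(rows) + 1L]] <- data.frame(
      from = d$item, to = d$covariate, type = "DIF", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
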