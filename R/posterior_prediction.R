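#' Posterior predictive datasets
#'
#' Simulates replicate experiments from draws of the fitted posterior: each
#' replicate picks one post-warmup draw (uniformly without replacement; with
#' replacement plus a warning when more replicates than draws are
#' requested), plugs its individual-level parameters into the trial-level
#' dynamics, and simulates choices and response times on the same trial
#' skeleton as the fitted data, preserving participant structure.
#'
#' @param fit a `ddm_fit` with its dataset attached (or pass `template`).
#' @param n_rep number of replicate datasets.
#' @param seed integer seed.
#' @param template optional [dd_dataset()] whose stimulus sequences are
#'   reused; defaults to the fitted dataset.
#' @param dt,t_max simulator controls, see [simulate_choice_rt()].
#' @return list of [dd_dataset()] replicates.
#' @export
posterior_predictive_datasets <- function(fit, n_rep = 500, seed = NULL,
                                          template = NULL, dt = 1e-4,
                                          t_max = 30) {
  template <- template %||% fit$dataset
  if (is.null(template)) stop_domain("no dataset stored in fit; pass template")
  spec <- fit$spec
  pn <- param_names(spec)
  pm <- posterior_matrix(fit)
  S <- nrow(pm)
  run <- function() {
    draw_idx <- if (n_rep <= S) sample.int(S, n_rep) else {
      warning("more replicates than posterior draws: sampling draws with replacement")
      sample.int(S, n_rep, replace = TRUE)
    }
    ids <- intersect(participants(template), fit$participant_ids)
    if (!length(ids)) stop_domain("template shares no participants with the fit")
    lapply(draw_idx, function(s) {
      trials <- template$trials[template$trials$participant_id %in% ids, , drop = FALSE]
      for (pid in ids) {
        idx <- which(trials$participant_id == pid)
        vals <- setNames(pm[s, paste0(pn, "[", pid, "]")], pn)
        params <- do.call(individual_parameters, as.list(vals))
        dyn <- dataset_dynamics(spec, params, trials[idx, , drop = FALSE],
                                standard_ms = fit$standard_ms, strict = FALSE)
        dyn$z_n[!dyn$valid] <- NA
        sim <- simulate_trials_cpp(dyn$v_n, pmin(pmax(dyn$z_n, 1e-6), 1 - 1e-6),
                                   params$a, params$tau, dt, t_max, TRUE)
        trials$response[idx] <- ifelse(is.na(sim$choice), NA_character_,
                                       ifelse(sim$choice == 1L, "first_longer",
                                              "second_longer"))
        trials$rt_s[idx] <- sim$rt_s
      }
      dd_dataset(trials[!is.na(trials$response), , drop = FALSE],
                 design = template$design,
                 provenance = "posterior predictive replicate")
    })
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "ppc"), run())
}

cell_stats <- function(trials, standard_ms, probs) {
  tr <- annotate_comparison(trials)
  tr <- tr[!is.na(tr$comparison_longer), , drop = FALSE]
  cells <- unique(tr[, c("comparison_ms", "order")])
  cells <- cells[order(cells$order, cells$comparison_ms), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(j) {
    sel <- tr$comparison_ms == cells$comparison_ms[j] & tr$order == cells$order[j]
    rt <- tr$rt_s[sel]
    q <- quantile(rt, probs = probs, names = FALSE, type = 7)
    data.frame(comparison_ms = cells$comparison_ms[j], order = cells$order[j],
               statistic = c("p_comparison_longer",
                             paste0("rt_q", round(100 * probs))),
               value = c(mean(tr$comparison_longer[sel]), q),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior predictive summary of choices and response times
#'
#' Per (comparison level x order) cell: the replicate distribution of the
#' probability of judging the comparison longer and of the pooled RT
#' quantiles (10/30/50/70/90%; the median is the 50% quantile), each
#' summarized by its mean and 95% HDI, next to the same statistics of the
#' empirical data and a coverage indicator (empirical value inside the
#' predicted HDI). RTs are pooled across participants within a cell;
#' per-participant summaries are available via `by_participant`.
#'
#' @param replicates list of replicate datasets
#'   ([posterior_predictive_datasets()]); at least 50 for the HDIs.
#' @param empirical the observed [dd_dataset()].
#' @param standard_ms standard duration; defaults to the empirical design.
#' @param probs RT quantile levels.
#' @param mass HDI mass.
#' @param by_participant if `TRUE`, cells are split by participant.
#' @return data frame of class `ppc_summary`: one row per cell x statistic
#'   with `predicted_mean`, `hdi_lower`, `hdi_upper`, `empirical`,
#'   `covered`. Cells empty in the empirical data are flagged with `NA`
#'   coverage and excluded from coverage claims.
#' @export
ppc_summary <- function(replicates, empirical, standard_ms = NULL,
                        probs = c(0.1, 0.3, 0.5, 0.7, 0.9), mass = 0.95,
                        by_participant = FALSE) {
  standard_ms <- standard_ms %||% (empirical$design$standard_ms %||% 500)
  split_units <- function(ds) {
    if (!by_participant) list(all = ds$trials)
    else split(ds$trials, ds$trials$participant_id)
  }
  emp_units <- split_units(empirical)
  out <- lapply(names(emp_units), function(un) {
    emp <- cell_stats(emp_units[[un]], standard_ms, probs)
    rep_stats <- lapply(replicates, function(r) {
      tr <- if (by_participant)
        r$trials[r$trials$participant_id == un, , drop = FALSE] else r$trials
      cell_stats(tr, standard_ms, probs)
    })
    key <- function(d) paste(d$comparison_ms, d$order, d$statistic)
    emp_key <- key(emp)
    mat <- vapply(rep_stats, function(d) {
      d$value[match(emp_key, key(d))]
    }, numeric(nrow(emp)))
    sm <- t(apply(mat, 1, function(v) {
      v <- v[is.finite(v)]
      h <- hdi(v, mass)
      c(mean(v), h)
    }))
    res <- data.frame(unit = un, emp[, c("comparison_ms", "order", "statistic")],
                      predicted_mean = sm[, 1], hdi_lower = sm[, 2],
                      hdi_upper = sm[, 3], empirical = emp$value,
                      stringsAsFactors = FALSE)
    res$covered <- ifelse(is.finite(res$empirical),
                          res$empirical >= res$hdi_lower &
                          res$empirical <= res$hdi_upper, NA)
    res
  })
  out <- do.call(rbind, out)
  if (!by_participant) out$unit <- NULL
  class(out) <- c("ppc_summary", class(out))
  out
}

#' Write a posterior predictive summary as delimited text
#' @param summary a [ppc_summary()] data frame.
#' @param path output file.
#' @export
write_ppc_summary <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE, na = "")
  invisible(path)
}
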