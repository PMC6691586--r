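#' Drug candidates for a process
#'
#' Joins the top-`k` hubs of a process subnetwork against a drug-target
#' table: any drug whose target matches a hub (by protein id or mapped gene)
#' is a candidate for inhibiting the process.  A process with no candidate in
#' its top-`k` hubs is *undruggable* at this `k`.
#'
#' @param s a `subnetwork`.
#' @param drugs tibble from [read_drug_table()] (`target`, `drug`).
#' @param k number of top hubs to consider (default 3).
#' @return tibble `process`, `drug`, `target`, `protein_id`, `hub_score`;
#'   zero rows if the process is undruggable.
#' @export
process_drug_candidates <- function(s, drugs, k = 3) {
  stopifnot(inherits(s, "subnetwork"), is.data.frame(drugs))
  hubs <- rank_hubs(s, k = min(k, nrow(s$nodes)))
  cand <- drugs |>
    dplyr::inner_join(hubs, by = dplyr::join_by("target" == "gene")) |>
    dplyr::bind_rows(
      drugs |>
        dplyr::inner_join(hubs |> dplyr::filter(.data$gene != .data$protein_id),
                          by = dplyr::join_by("target" == "protein_id")) |>
        dplyr::rename(protein_id = "target") |>
        dplyr::mutate(target = .data$protein_id)
    ) |>
    dplyr::distinct(.data$drug, .data$protein_id, .keep_all = TRUE) |>
    dplyr::mutate(process = s$process) |>
    dplyr::select("process", "drug", "target", "protein_id", "hub_score") |>
    dplyr::arrange(.data$drug, .data$protein_id)
  cand
}

#' Design a per-sample drug combination
#'
#' Chooses a drug set so that every active process of the sample is covered
#' by at least one drug hitting one of its hub proteins, per the
#' target-every-active-process principle.  Selection is greedy weighted set
#' cover: repeatedly pick the drug covering the most still-uncovered
#' processes, breaking ties by the larger summed hub score over those
#' processes, then alphabetically — so plans are deterministic.  Greedy
#' always completes the cover whenever a complete cover exists; processes
#' with no candidate drug are reported as `uncovered`.
#'
#' When `boost_factor` is set, processes whose sample amplitude magnitude is
#' at least `boost_factor` times the cohort median magnitude for that process
#' demand coverage by two distinct drugs (an extra drug for exceptionally
#' strong processes).
#'
#' @param active tibble for one sample from [active_processes()]
#'   (columns `process`, `amplitude`).
#' @param candidates tibble of per-process candidates, e.g. rows of
#'   [process_drug_candidates()] over all processes.
#' @param method `"greedy"` (default) or `"exhaustive"` (minimum-size cover
#'   by enumeration; only for small active sets).
#' @param boost_factor optional numeric; enables the double-coverage rule
#'   (typical value 2).
#' @param cohort_median_amp named numeric vector of per-process cohort median
#'   `|amplitude|`; required when `boost_factor` is set.
#' @param sample_id carried into the plan.
#' @return a `combination_plan`: list with `sample_id`, `drugs` (tibble
#'   `drug`, `processes` list-column, `targets` list-column), `active`,
#'   `boosted`, `uncovered` (process indices), `complete` (logical).
#' @export
design_combination <- function(active, candidates,
                               method = c("greedy", "exhaustive"),
                               boost_factor = NULL, cohort_median_amp = NULL,
                               sample_id = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.data.frame(active))
  procs <- as.integer(active$process)
  need <- setNames(rep(1L, length(procs)), procs)
  boosted <- integer(0)
  if (!is.null(boost_factor)) {
    if (is.null(cohort_median_amp)) abort("`cohort_median_amp` is required with `boost_factor`.")
    med <- cohort_median_amp[as.character(procs)]
    hot <- !is.na(med) & med > 0 & abs(active$amplitude) >= boost_factor * med
    boosted <- procs[hot]
    need[as.character(boosted)] <- 2L
  }

  if (nrow(candidates) == 0) {
    cand <- tibble(drug = character(0), process = integer(0),
                   hub_score = numeric(0), target = character(0))
  } else {
    cand <- candidates |>
      dplyr::filter(.data$process %in% procs)
  }
  # per-drug covered process set and per-(drug, process) best hub score
  if (nrow(cand) == 0) {
    dp <- tibble(drug = character(0), process = integer(0),
                 hub_score = numeric(0), targets = list())
  } else {
    dp <- cand |>
      dplyr::group_by(.data$drug, .data$process) |>
      dplyr::summarise(hub_score = max(.data$hub_score),
                       targets = list(unique(.data$target)), .groups = "drop")
  }

  chosen <- character(0)
  remaining <- need
  drugs_left <- unique(dp$drug)
  while (any(remaining > 0) && length(drugs_left) > 0) {
    gain <- purrr::map_dfr(drugs_left, function(dr) {
      cov <- dp$process[dp$drug == dr]
      cov <- cov[remaining[as.character(cov)] > 0]
      tibble(drug = dr, n_cover = length(cov),
             score = sum(dp$hub_score[dp$drug == dr & dp$process %in% cov]))
    }) |>
      dplyr::filter(.data$n_cover > 0) |>
      dplyr::arrange(dplyr::desc(.data$n_cover), dplyr::desc(.data$score), .data$drug)
    if (nrow(gain) == 0) break
    pick <- gain$drug[1]
    chosen <- c(chosen, pick)
    cov <- as.character(dp$process[dp$drug == pick])
    remaining[cov] <- pmax(0L, remaining[cov] - 1L)
    drugs_left <- setdiff(drugs_left, pick)
  }

  if (method == "exhaustive" && any(need > 0)) {
    best <- exhaustive_cover(dp, need)
    if (!is.null(best) && length(best) < length(chosen)) chosen <- best
  }

  uncovered <- as.integer(names(remaining)[remaining > 0])
  if (method == "exhaustive") {
    # recompute residual need for the chosen set
    rem <- need
    for (dr in chosen) {
      cov <- as.character(dp$process[dp$drug == dr])
      rem[cov] <- pmax(0L, rem[cov] - 1L)
    }
    uncovered <- as.integer(names(rem)[rem > 0])
  }

  drug_tbl <- tibble(drug = character(0), processes = list(), targets = list())
  if (length(chosen) > 0) {
    drug_tbl <- purrr::map_dfr(chosen, function(dr) {
      rows <- dp[dp$drug == dr, ]
      tibble(drug = dr,
             processes = list(sort(as.integer(rows$process))),
             targets = list(sort(unique(unlist(rows$targets)))))
    })
  }
  structure(
    list(sample_id = sample_id, drugs = drug_tbl,
         active = procs, boosted = boosted,
         uncovered = sort(uncovered),
         complete = length(uncovered) == 0),
    class = "combination_plan"
  )
}

# minimum-cardinality multi-cover by enumeration over drug subsets;
# ties resolved towards the lexicographically smallest drug set.
exhaustive_cover <- function(dp, need) {
  drugs <- sort(unique(dp$drug))
  nd <- length(drugs)
  if (nd == 0 || nd > 15) return(NULL)
  covers <- lapply(drugs, function(dr) as.character(dp$process[dp$drug == dr]))
  best <- NULL
  for (size in seq_len(nd)) {
    combs <- utils::combn(nd, size, simplify = FALSE)
    for (cc in combs) {
      rem <- need
      for (j in cc) rem[covers[[j]]] <- pmax(0L, rem[covers[[j]]] - 1L)
      if (all(rem == 0)) { best <- drugs[cc]; break }
    }
    if (!is.null(best)) break
  }
  best
}

#' @export
print.combination_plan <- function(x, ...) {
  cat("<combination_plan> ", x$sample_id, ": ", nrow(x$drugs), " drug(s) for ",
      length(x$active), " active process(es)",
      if (!x$complete) paste0("; UNCOVERED: ", paste(x$uncovered, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy combination_plan
#' @export
tidy.combination_plan <- function(x, ...) {
  if (nrow(x$drugs) == 0) {
    return(tibble(sample_id = character(0), drug = character(0),
                  processes = character(0), targets = character(0)))
  }
  tibble(
    sample_id = x$sample_id,
    drug = x$drugs$drug,
    processes = purrr::map_chr(x$drugs$processes, paste, collapse = ","),
    targets = purrr::map_chr(x$drugs$targets, paste, collapse = ",")
  )
}

#' Design combinations for every sample of a cohort
#'
#' Runs [process_drug_candidates()] per significant process and
#' [design_combination()] per sample.
#'
#' @inheritParams design_combination
#' @param d a `surprisal_decomp`.
#' @param model a `significance_model`.
#' @param graph an `interaction_graph`.
#' @param drugs drug-target tibble.
#' @param alias optional antibody-to-gene alias map.
#' @param hub_k top hubs considered per process (default 3).
#' @return named list of `combination_plan`s, one per sample.
#' @export
design_cohort_combinations <- function(d, model, graph, drugs, alias = NULL,
                                       hub_k = 3, boost_factor = NULL) {
  act_all <- active_processes(d, model)
  cands <- purrr::map_dfr(seq_len(model$m_star), function(a) {
    pp <- suppressWarnings(process_proteins(d, model, a))
    if (nrow(pp) == 0) return(tibble())
    process_drug_candidates(build_subnetwork(pp, graph, alias, process = a),
                            drugs, k = hub_k)
  })
  med <- NULL
  if (!is.null(boost_factor)) {
    lam <- d$lambda[seq_len(model$m_star) + 1L, , drop = FALSE]
    med <- setNames(apply(abs(lam), 1, median), as.character(seq_len(model$m_star)))
  }
  plans <- lapply(sample_ids(d), function(k) {
    design_combination(act_all[act_all$sample_id == k, , drop = FALSE], cands,
                       boost_factor = boost_factor, cohort_median_amp = med,
                       sample_id = k)
  })
  setNames(plans, sample_ids(d))
}

#' Write combination plans
#'
#' TSV with one row per (sample, drug) plus a JSON file mirroring the plan
#' objects.
#'
#' @param plans list of `combination_plan`s.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the tidied plan tibble.
#' @export
write_plans <- function(plans, tsv_path = NULL, json_path = NULL) {
  tidied <- purrr::map_dfr(plans, tidy)
  if (!is.null(tsv_path)) readr::write_tsv(tidied, tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(plans, function(p) {
      list(sample_id = p$sample_id, active = p$active, boosted = p$boosted,
           uncovered = p$uncovered, complete = p$complete,
           drugs = lapply(seq_len(nrow(p$drugs)), function(i) {
             list(drug = p$drugs$drug[i],
                  processes = p$drugs$processes[[i]],
                  targets = p$drugs$targets[[i]])
           }))
    }), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tidied)
}
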