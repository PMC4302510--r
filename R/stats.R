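#' Knockout impact summary
#'
#' Summarizes how much of the network a knockout switches off, at the
#' level of partial-coupling classes and of individual reactions.
#'
#' * Single knockouts: for each class representative `r`, the impact is
#'   the number of classes other than `[r]` whose reactions are blocked by
#'   knocking out `r` (in the reaction variant, the number of reactions in
#'   those classes); averaged over all representatives.
#' * Double knockouts: the *additional* impact of an analysed pair
#'   \{r, s\} is its number of jointly coupled target classes (resp.
#'   target reactions); averaged over the pairs that have a joint effect
#'   at all.  The ratio reports what fraction of the candidate pairs that
#'   is.
#'
#' @param dko a [double_knockout_analysis()] result.
#' @return An object of class `impact_summary` with fields `n_unblocked`,
#'   `n_classes`, `single_mean_classes`, `single_mean_reactions`,
#'   `double_mean_additional_classes`, `double_mean_additional_reactions`,
#'   `double_ratio_percent`, `n_candidate_pairs`, `n_effective_pairs`.
#' @export
impact_stats <- function(dko) {
  stopifnot(inherits(dko, "dko_analysis"))
  table <- dko$table
  reps <- table$representatives
  if (!length(reps)) stop("impact statistics are undefined: no unblocked reactions")
  class_size <- vapply(table$classes, length, integer(1))

  blocked_classes <- function(r) {
    after <- max_without(table, r)
    others <- setdiff(reps, table$class_map[[r]])
    others[!(others %in% after)]  # whole classes vanish together
  }
  single_cls <- vapply(reps, function(r) length(blocked_classes(r)), numeric(1))
  single_rxn <- vapply(reps, function(r) {
    sum(class_size[blocked_classes(r)])
  }, numeric(1))

  eff <- Filter(function(rec) rec$has_joint_effect, dko$records)
  target_classes <- function(rec) unique(table$class_map[rec$targets])
  double_cls <- vapply(eff, function(rec) length(target_classes(rec)), numeric(1))
  double_rxn <- vapply(eff, function(rec) length(rec$targets), numeric(1))

  structure(list(
    n_unblocked = length(table$unblocked),
    n_classes = length(reps),
    single_mean_classes = mean(single_cls),
    single_mean_reactions = mean(single_rxn),
    double_mean_additional_classes = if (length(eff)) mean(double_cls) else NA_real_,
    double_mean_additional_reactions = if (length(eff)) mean(double_rxn) else NA_real_,
    double_ratio_percent = if (length(dko$records)) {
      100 * length(eff) / length(dko$records)
    } else NA_real_,
    n_candidate_pairs = length(dko$records),
    n_effective_pairs = length(eff)
  ), class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat("<impact_summary>\n",
      "  unblocked reactions: ", x$n_unblocked, "\n",
      "  coupling classes:    ", x$n_classes, "\n",
      sprintf("  single KO impact:    %.3g classes (%.3g reactions)\n",
              x$single_mean_classes, x$single_mean_reactions),
      sprintf("  double KO impact:    %.3g classes (%.3g reactions), ratio %.3g%% (%d / %d pairs)\n",
              x$double_mean_additional_classes,
              x$double_mean_additional_reactions,
              x$double_ratio_percent, x$n_effective_pairs,
              x$n_candidate_pairs),
      sep = "")
  invisible(x)
}

#' Knockout option summary
#'
#' The target's perspective: for every unblocked reaction `t`, how many
#' single reactions `r` satisfy `r -> t` (classmates of `t` count), and
#' how many reaction pairs block `t` jointly?  Counting is at reaction
#' level: a representative-level joint coupling \{r, s\} -> t expands to
#' `|[r]| * |[s]|` knockout options for each of the `|[t]|` classmates of
#' `t`.  Both counts are averaged over all unblocked reactions.
#'
#' @param dko a [double_knockout_analysis()] result.
#' @return An object of class `option_summary` with
#'   `single_mean_options` and `double_mean_options`.
#' @export
option_stats <- function(dko) {
  stopifnot(inherits(dko, "dko_analysis"))
  table <- dko$table
  ub <- table$unblocked
  if (!length(ub)) stop("option statistics are undefined: no unblocked reactions")
  class_size <- vapply(table$classes, length, integer(1))

  single <- vapply(ub, function(t) {
    sum(vapply(setdiff(ub, t), function(r) is_coupled(table, r, t),
               logical(1)))
  }, numeric(1))

  # collapse records to unique representative pairs (handles variant A)
  pair_opts <- stats::setNames(numeric(length(ub)), ub)
  seen <- character()
  for (rec in dko$records) {
    if (!rec$has_joint_effect) next
    k <- record_class_key(rec, table)
    key <- paste(k$pair, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    n_opts <- class_size[[k$pair[1]]] * class_size[[k$pair[2]]]
    tgt_rxns <- unlist(table$classes[k$targets], use.names = FALSE)
    pair_opts[tgt_rxns] <- pair_opts[tgt_rxns] + n_opts
  }

  structure(list(single_mean_options = mean(single),
                 double_mean_options = mean(pair_opts)),
            class = "option_summary")
}

#' @export
print.option_summary <- function(x, ...) {
  cat(sprintf("<option_summary> single %.4g, double %.4g knockout options per target\n",
              x$single_mean_options, x$double_mean_options))
  invisible(x)
}

#' Knockouts that block the biomass reaction
#'
#' Counts the single and double knockouts that block a designated biomass
#' reaction.  Singles: classes (and their reactions) directionally
#' coupled to the biomass, excluding the biomass's own partial-coupling
#' class.  Doubles: analysed representative pairs whose joint targets
#' contain the biomass reaction — by the definition of joint coupling
#' neither pair member is directionally coupled to the biomass — expanded
#' to reaction pairs by the product of class sizes.
#'
#' @param dko a [double_knockout_analysis()] result.
#' @param biomass_id an unblocked reaction id.
#' @return An object of class `biomass_summary` with fields
#'   `biomass_reaction_id`, `class_size`, `single_classes`,
#'   `single_reactions`, `double_class_pairs`, `double_reaction_pairs`.
#' @export
biomass_blockers <- function(dko, biomass_id) {
  stopifnot(inherits(dko, "dko_analysis"))
  table <- dko$table
  if (!biomass_id %in% table$unblocked) {
    stop("biomass reaction '", biomass_id, "' is blocked or unknown")
  }
  class_size <- vapply(table$classes, length, integer(1))
  b_rep <- table$class_map[[biomass_id]]
  blocking_reps <- Filter(function(r) {
    r != b_rep && !(biomass_id %in% max_without(table, r))
  }, table$representatives)

  seen <- character()
  n_class_pairs <- 0L
  n_rxn_pairs <- 0
  for (rec in dko$records) {
    if (!rec$has_joint_effect || !(biomass_id %in% rec$targets)) next
    k <- record_class_key(rec, table)
    key <- paste(k$pair, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    n_class_pairs <- n_class_pairs + 1L
    n_rxn_pairs <- n_rxn_pairs + class_size[[k$pair[1]]] * class_size[[k$pair[2]]]
  }

  structure(list(
    biomass_reaction_id = biomass_id,
    class_size = class_size[[b_rep]],
    single_classes = length(blocking_reps),
    single_reactions = sum(class_size[unlist(blocking_reps, use.names = FALSE)]),
    double_class_pairs = n_class_pairs,
    double_reaction_pairs = n_rxn_pairs
  ), class = "biomass_summary")
}

#' @export
print.biomass_summary <- function(x, ...) {
  cat("<biomass_summary> ", x$biomass_reaction_id,
      " (class size ", x$class_size, ")\n",
      "  single knockouts: ", x$single_classes, " classes / ",
      x$single_reactions, " reactions\n",
      "  double knockouts: ", x$double_class_pairs, " class pairs / ",
      x$double_reaction_pairs, " reaction pairs\n", sep = "")
  invisible(x)
}
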