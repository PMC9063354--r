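#' Build discordant homoeolog pair records for one subgenome pairing
#'
#' Restricts homoeolog groups to those with exactly one gene on each of the
#' two requested subgenomes (1:1 correspondence), attaches expression and a
#' per-gene transcribed-enhancer flag, and keeps the discordant pairs: one
#' homoeolog associated with at least one linked transcribed enhancer on its
#' own chromosome while the other is not. Trans-chromosomal links never set
#' the flag.
#'
#' @param genes Gene-model tibble with `subgenome` and `homoeolog_group`
#'   columns.
#' @param expression Expression tibble (`gene_id`, `level`).
#' @param links Enhancer-target links ([assign_targets()]); the `chrom`
#'   column is the enhancer's chromosome.
#' @param subgenomes Character vector of length 2, e.g. `c("A", "B")`; the
#'   first is reported as side `a`.
#' @param discordant_only Keep only discordant pairs (default TRUE, the
#'   odds-ratio input).
#' @return A tibble `group_id`, `gene_a`, `gene_b`, `expr_a`, `expr_b`,
#'   `enh_a`, `enh_b`, `pairing`.
#' @export
build_homoeolog_pairs <- function(genes, expression, links,
                                  subgenomes = c("A", "B"),
                                  discordant_only = TRUE) {
  stopifnot(length(subgenomes) == 2)
  if (any(expression$level < 0)) abort("expression levels must be >= 0")
  flagged <- genes |>
    filter(.data$subgenome %in% subgenomes) |>
    left_join(expression, by = "gene_id")
  # same-chromosome rule: a link counts only if the enhancer sits on the
  # gene's own chromosome

  cis <- links |>
    semi_join(flagged, by = "gene_id") |>
    inner_join(select(flagged, "gene_id", gene_chrom = "chrom"),
               by = "gene_id") |>
    filter(.data$chrom == .data$gene_chrom) |>
    distinct(.data$gene_id)
  flagged <- mutate(flagged, enh = .data$gene_id %in% cis$gene_id)

  one_one <- flagged |>
    count(.data$homoeolog_group, .data$subgenome) |>
    tidyr::pivot_wider(names_from = "subgenome", values_from = "n",
                       values_fill = 0) |>
    filter(if_all(all_of(subgenomes), ~ .x == 1)) |>
    pull(.data$homoeolog_group)

  side <- function(sg, suffix) {
    flagged |>
      filter(.data$subgenome == sg, .data$homoeolog_group %in% one_one) |>
      select(group_id = "homoeolog_group",
             !!paste0("gene_", suffix) := "gene_id",
             !!paste0("expr_", suffix) := "level",
             !!paste0("enh_", suffix) := "enh")
  }
  pairs <- inner_join(side(subgenomes[1], "a"), side(subgenomes[2], "b"),
                      by = "group_id") |>
    mutate(pairing = paste(subgenomes, collapse = "-"))
  if (any(is.na(pairs$expr_a) | is.na(pairs$expr_b))) {
    abort("expression missing for some homoeolog pair members")
  }
  if (discordant_only) pairs <- filter(pairs, xor(.data$enh_a, .data$enh_b))
  pairs
}

#' Call expression bias within a homoeolog pair
#'
#' Fold-change gate: side `a` is the higher-expressed homoeolog when
#' `expr_a >= fc_threshold * expr_b` and `expr_a >= min_expr` (symmetrically
#' for `b`); otherwise the pair is balanced. The `min_expr` floor guards
#' zero-expression artifacts (so 1 vs 0 is a valid dominance call but
#' 0.01 vs 0 is not).
#'
#' @param pairs Pair tibble ([build_homoeolog_pairs()]).
#' @param fc_threshold Dominance fold change (default 2).
#' @param min_expr Minimum expression of the dominant side (default 0.5).
#' @return `pairs` with a `bias` column (`a_higher` / `b_higher` /
#'   `balanced`).
#' @export
bias_call <- function(pairs, fc_threshold = 2, min_expr = 0.5) {
  stopifnot(fc_threshold > 0, min_expr > 0)
  if (any(pairs$expr_a < 0 | pairs$expr_b < 0)) {
    abort("expression must be >= 0")
  }
  mutate(pairs, bias = case_when(
    .data$expr_a >= fc_threshold * .data$expr_b & .data$expr_a >= min_expr ~ "a_higher",
    .data$expr_b >= fc_threshold * .data$expr_a & .data$expr_b >= min_expr ~ "b_higher",
    TRUE ~ "balanced"
  ))
}

#' Contingency table of enhancer side versus dominant side
#'
#' Rows split the discordant pairs by which homoeolog bears the transcribed
#' enhancer; columns record whether homoeolog `a` is the dominant one.
#' Reading the cells: `a` = enhancer on `a` and `a` dominant (the
#' enhancer-bearing homoeolog is the higher one), `b` = enhancer on `a` but
#' `a` not higher; `c`/`d` mirror this for pairs whose enhancer sits on `b`
#' (there the `a` homoeolog is the enhancer-free one). Balanced pairs fall in
#' the "not higher" cells. Because each pair contributes to exactly one row,
#' the two rows are independent samples and the classical odds-ratio
#' standard error applies.
#'
#' @param pairs Discordant pair tibble with `bias` ([bias_call()]).
#' @return A 2x2 integer matrix with dimnames
#'   `enhancer = c("on_a", "on_b")`, `expression = c("a_higher",
#'   "not_a_higher")`.
#' @export
pair_contingency <- function(pairs) {
  if (nrow(pairs) == 0) abort("no discordant pairs to tabulate")
  if (!"bias" %in% names(pairs)) abort("run bias_call() first")
  if (!all(xor(pairs$enh_a, pairs$enh_b))) {
    abort("contingency requires discordant pairs (enh_a XOR enh_b)")
  }
  a_high <- pairs$bias == "a_higher"
  matrix(
    c(sum(pairs$enh_a & a_high), sum(pairs$enh_a & !a_high),
      sum(pairs$enh_b & a_high), sum(pairs$enh_b & !a_high)),
    nrow = 2, byrow = TRUE,
    dimnames = list(enhancer = c("on_a", "on_b"),
                    expression = c("a_higher", "not_a_higher"))
  )
}

#' Odds ratio with Haldane-Anscombe correction and Wald CI
#'
#' `OR = (a/b) / (c/d)` for the table `(a, b; c, d)`. When any cell is zero
#' and `haldane` is TRUE, 0.5 is added to every cell (the Haldane-Anscombe
#' small-sample correction). The log-OR standard error is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% CI is
#' `exp(log OR +/- 1.96 * SE)`.
#'
#' @param table A 2x2 matrix (rows = groups, as from [pair_contingency()]) or
#'   a length-4 vector `(a, b, c, d)`.
#' @param haldane Apply the 0.5 correction when a zero cell is present?
#' @return An object of class `or_result` with `estimate`, `log_or`, `se`,
#'   `conf_low`, `conf_high`, the raw and corrected tables, and `n` (total
#'   classified pairs). Supports [tidy()], [glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @export
odds_ratio <- function(table, haldane = TRUE) {
  cells <- as.numeric(t(table))
  if (length(cells) != 4 || any(cells < 0)) {
    abort("odds_ratio() needs four non-negative counts (a, b, c, d)")
  }
  if (sum(cells) == 0) abort("all-zero contingency table")
  corrected <- haldane && any(cells == 0)
  used <- if (corrected) cells + 0.5 else cells
  log_or <- log(used[1]) - log(used[2]) - log(used[3]) + log(used[4])
  se <- sqrt(sum(1 / used))
  structure(
    list(
      table = matrix(cells, nrow = 2, byrow = TRUE,
                     dimnames = list(group = c("row1", "row2"),
                                     outcome = c("yes", "no"))),
      table_used = matrix(used, nrow = 2, byrow = TRUE),
      estimate = exp(log_or),
      log_or = log_or,
      se = se,
      conf_low = exp(log_or - 1.96 * se),
      conf_high = exp(log_or + 1.96 * se),
      haldane_applied = corrected,
      n = sum(cells)
    ),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("Odds ratio: %.3f (95%% CI %.3f-%.3f)%s\n",
              x$estimate, x$conf_low, x$conf_high,
              if (x$haldane_applied) " [Haldane-corrected]" else ""))
  print(x$table)
  invisible(x)
}

#' @rdname odds_ratio
#' @param x An `or_result`.
#' @param ... Unused.
#' @export
tidy.or_result <- function(x, ...) {
  tibble(
    estimate = x$estimate, log_or = x$log_or, std_error = x$se,
    conf_low = x$conf_low, conf_high = x$conf_high
  )
}

#' @rdname odds_ratio
#' @export
glance.or_result <- function(x, ...) {
  tibble(n = x$n, haldane_applied = x$haldane_applied)
}

#' Pooled dominance odds ratio over all subgenome pairings
#'
#' Sums the per-pairing contingency tables (equivalently, tabulates the
#' pooled discordant records) and computes one odds ratio: do dominantly
#' expressed homoeologs associate with transcribed enhancers across the
#' whole genome?
#'
#' @param pairs_list A list of (or a single) discordant pair tibbles with
#'   `bias` columns, one per subgenome pairing.
#' @param haldane Passed to [odds_ratio()].
#' @return An `or_result` for the pooled table.
#' @export
merged_dominance_or <- function(pairs_list, haldane = TRUE) {
  if (is.data.frame(pairs_list)) pairs_list <- list(pairs_list)
  tables <- lapply(pairs_list, pair_contingency)
  odds_ratio(Reduce(`+`, tables), haldane = haldane)
}
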