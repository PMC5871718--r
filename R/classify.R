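#' Classify HSP90 (chaperone) dependence from significance calls
#'
#' A protein is chaperone dependent when it is significantly downregulated
#' upon chaperone inhibition in at least one time point. Significant
#' downregulation of the mature pool at any time point classifies the
#' protein as constitutively dependent, irrespective of the nascent pool.
#' Significant downregulation only in the nascent pool classifies it as
#' dependent during synthesis. Proteins never significantly downregulated
#' are not regulated; upregulation (stabilization) is reported as direction
#' metadata, not a class. Proteins quantified in only one pool are
#' classified from that pool alone and flagged partial.
#'
#' @param calls Data frame of significance calls with columns
#'   `protein_group`, `time_point`, `pool`, `significant`, `direction`.
#' @return A tibble per protein: `class` (`"constitutive"`, `"synthesis"`,
#'   `"not_regulated"`), supporting time points per pool, an `any_up` flag,
#'   and `partial` marking single-pool evidence.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   protein_group = c("P1", "P1", "P2", "P2"),
#'   time_point = c(6, 6, 8, 24),
#'   pool = c("mature", "nascent", "nascent", "nascent"),
#'   significant = c(TRUE, FALSE, TRUE, TRUE),
#'   direction = c("down", "none", "down", "down")
#' )
#' classify_dependence(calls)
classify_dependence <- function(calls) {
  check_columns(calls,
                c("protein_group", "time_point", "pool", "significant", "direction"),
                "significance-call table")
  as_tibble(calls) |>
    group_by(.data$protein_group) |>
    summarise(
      mature_down_at = list(sort(unique(.data$time_point[
        .data$pool == "mature" & .data$significant & .data$direction == "down"]))),
      nascent_down_at = list(sort(unique(.data$time_point[
        .data$pool == "nascent" & .data$significant & .data$direction == "down"]))),
      any_up = any(.data$significant & .data$direction == "up"),
      partial = n_distinct(.data$pool) < 2,
      .groups = "drop"
    ) |>
    mutate(
      class = case_when(
        lengths(.data$mature_down_at) > 0 ~ "constitutive",
        lengths(.data$nascent_down_at) > 0 ~ "synthesis",
        TRUE ~ "not_regulated"
      )
    ) |>
    select("protein_group", "class", "mature_down_at", "nascent_down_at",
           "any_up", "partial")
}

#' Enrichment of an annotation among classified proteins
#'
#' Builds the 2x2 contingency table of class membership versus annotation
#' over a background of identified proteins and evaluates enrichment with
#' Fisher's exact test (two-sided hypergeometric p). The odds ratio reported
#' is the sample odds ratio (ad/bc).
#'
#' @param class_members Protein identifiers in the class of interest (e.g.
#'   constitutively dependent proteins).
#' @param annotation Protein identifiers carrying the annotation (e.g. a
#'   published chaperone-interactor list).
#' @param background All identified protein identifiers; must contain
#'   `class_members` and overlap `annotation`.
#' @return A tibble with the four contingency counts, `odds_ratio`,
#'   `p_value`, and a `flag` for degenerate margins (where p = 1).
#' @export
fisher_enrichment <- function(class_members, annotation, background) {
  background <- unique(background)
  class_members <- unique(intersect(class_members, background))
  annotation <- unique(intersect(annotation, background))
  if (length(annotation) == 0) {
    abort("annotation list is disjoint from the background")
  }
  in_class <- background %in% class_members
  in_annot <- background %in% annotation
  a <- sum(in_class & in_annot)
  b <- sum(in_class & !in_annot)
  c_ <- sum(!in_class & in_annot)
  d <- sum(!in_class & !in_annot)
  tab <- matrix(c(a, c_, b, d), nrow = 2)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  tibble(
    class_annotated = a, class_other = b,
    rest_annotated = c_, rest_other = d,
    odds_ratio = (a * d) / (b * c_),
    p_value = p,
    flag = if (degenerate) "empty_margin" else NA_character_
  )
}
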