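# Co-culture growth assays: score pairwise OD600 outcomes against
# monoculture expectations and classify interactions.

#' Read a long-format co-culture OD table
#'
#' Expected columns: `strain_a`, `strain_b`, `condition` (`mono` or `co`),
#' `day`, `replicate`, `od600`.  Monoculture rows leave `strain_b` empty.
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
read_coculture <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_a", "strain_b", "condition", "day", "replicate", "od600")
  if (!all(need %in% colnames(d)))
    stop("co-culture table must have columns: ", paste(need, collapse = ", "))
  if (any(!d$condition %in% c("mono", "co")))
    stop("condition must be 'mono' or 'co'")
  if (any(is.na(d$od600) | d$od600 < 0)) stop("OD600 must be non-negative")
  d$strain_b[is.na(d$strain_b)] <- ""
  d
}

#' Inoculum normalisation factors
#'
#' Each starter culture is normalised to the lowest optical density:
#' `factor_i = min(OD) / OD_i`, so the lowest-OD strain gets factor 1 and
#' all factors are `<= 1`.
#'
#' @param od_by_strain named positive vector of starter-culture ODs.
#' @return named vector of scale factors.
#' @export
normalize_inocula <- function(od_by_strain) {
  if (any(od_by_strain <= 0)) stop("all ODs must be positive")
  min(od_by_strain) / od_by_strain
}

#' Expected co-culture optical density
#'
#' Combines the two day-3 monoculture means under a stated rule.  The rule
#' is a modelling choice surfaced explicitly: `"mean"` (default; a 1:1 mixed
#' inoculum approaching a shared carrying capacity), `"sum"` (fully
#' independent resource use) or `"max"`.
#'
#' @param mono_a_day3,mono_b_day3 day-3 monoculture mean ODs.
#' @param rule combining rule.
#' @return expected OD.
#' @export
expected_od <- function(mono_a_day3, mono_b_day3,
                        rule = c("mean", "sum", "max")) {
  rule <- match.arg(rule)
  if (is.na(mono_a_day3) || is.na(mono_b_day3))
    stop("both monoculture day-3 means are required")
  switch(rule,
         mean = (mono_a_day3 + mono_b_day3) / 2,
         sum = mono_a_day3 + mono_b_day3,
         max = max(mono_a_day3, mono_b_day3))
}

#' Classify a co-culture deviation against replicate spread
#'
#' `positive` iff the observed-minus-expected deviation exceeds one
#' replicate SD, `negative` iff below minus one SD, `neutral` otherwise
#' (strict inequalities: a deviation of exactly one SD is neutral).
#'
#' @param deviation observed minus expected OD (vectorised).
#' @param sd replicate standard deviation(s), `> 0` finite.
#' @return character vector in `positive` / `negative` / `neutral`.
#' @export
classify_interaction <- function(deviation, sd) {
  if (any(is.na(sd))) stop("replicate SD unavailable (need >= 2 replicates)")
  ifelse(deviation > sd, "positive",
         ifelse(deviation < -sd, "negative", "neutral"))
}

#' Score all co-culture records of an assay
#'
#' For every strain pair grown in co-culture, computes the expected day-3 OD
#' from the two monoculture day-3 means ([expected_od()]), the observed
#' co-culture mean and replicate SD, their deviation, and the interaction
#' class ([classify_interaction()]).
#'
#' @param data long-format assay table ([read_coculture()]).
#' @param rule expected-OD combining rule.
#' @param day assay endpoint day (default 3).
#' @return `data.frame` of class `coculture_records`.
#' @export
coculture_analysis <- function(data, rule = c("mean", "sum", "max"), day = 3) {
  rule <- match.arg(rule)
  mono <- data[data$condition == "mono" & data$day == day, ]
  mono_means <- tapply(mono$od600, mono$strain_a, mean)
  co <- data[data$condition == "co" & data$day == day, ]
  if (nrow(co) == 0L) stop("no co-culture rows at day ", day)
  key <- paste(pmin(co$strain_a, co$strain_b), pmax(co$strain_a, co$strain_b),
               sep = "\r")
  rows <- lapply(unique(key), function(k) {
    pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
    reps <- co$od600[key == k]
    if (length(reps) < 2L)
      stop("pair ", pair[1], " x ", pair[2],
           ": need >= 2 replicates for an SD")
    for (s in pair) if (is.na(mono_means[s]))
      stop("missing monoculture day-", day, " data for strain ", s)
    exp_od <- expected_od(mono_means[[pair[1]]], mono_means[[pair[2]]], rule)
    obs <- mean(reps)
    s <- sd(reps)
    data.frame(strain_a = pair[1], strain_b = pair[2],
               mono_a = mono_means[[pair[1]]], mono_b = mono_means[[pair[2]]],
               expected = exp_od, observed = obs, sd = s,
               deviation = obs - exp_od,
               class = classify_interaction(obs - exp_od, s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  attr(out, "day") <- day
  class(out) <- c("coculture_records", "data.frame")
  out
}

#' Strain-by-strain deviation matrix for heat-map plotting
#'
#' Symmetric matrix of observed-minus-expected OD deviations; untested pairs
#' and the diagonal are `NA`.  The same unordered pair recorded twice with
#' conflicting deviations is an error.
#'
#' @param records a `coculture_records` frame.
#' @return symmetric numeric matrix.
#' @export
heatmap_matrix <- function(records) {
  strains <- sort(unique(c(records$strain_a, records$strain_b)))
  m <- matrix(NA_real_, length(strains), length(strains),
              dimnames = list(strains, strains))
  for (i in seq_len(nrow(records))) {
    a <- records$strain_a[i]; b <- records$strain_b[i]
    v <- records$deviation[i]
    old <- m[a, b]
    if (!is.na(old) && abs(old - v) > 1e-12)
      stop("conflicting duplicate records for pair ", a, " x ", b)
    m[a, b] <- m[b, a] <- v
  }
  m
}
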