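#' Env lineage by reference scoring
#'
#' Stands in for the Env phylogeny: the env translation is locally aligned
#' against the beta and gamma Env reference families and assigned to the
#' family with the higher best score. When the two best scores differ by
#' less than `margin` (fraction of the larger), or neither clears `floor`,
#' the lineage is `unknown`. Some Type D betaretroviruses carry an Env that
#' clusters with gammaretroviruses; this is the feature the rule captures.
#'
#' @param env_translation env protein (>= 100 usable aa recommended).
#' @param beta_refs,gamma_refs named character vectors of reference Env
#'   proteins.
#' @param margin relative score margin below which the call is `unknown`.
#' @param floor minimum best score.
#' @param params alignment parameters.
#' @return list: `lineage` ("beta"/"gamma"/"unknown"), `score_beta`,
#'   `score_gamma`.
#' @export
env_lineage <- function(env_translation, beta_refs, gamma_refs,
                        margin = 0.05, floor = 50,
                        params = alignment_params(low_complexity_filter = FALSE)) {
  best <- function(refs) {
    if (length(refs) == 0) return(0)
    max(vapply(refs, function(r)
      local_align_protein(r, env_translation, params, score_only = TRUE)$score,
      1))
  }
  sb <- best(beta_refs); sg <- best(gamma_refs)
  top <- max(sb, sg)
  lineage <- if (top < floor) "unknown"
  else if (abs(sb - sg) < margin * top) "unknown"
  else if (sb > sg) "beta" else "gamma"
  list(lineage = lineage, score_beta = sb, score_gamma = sg)
}

#' Phylogenetic-placement proxy by Pol reference scoring
#'
#' Nearest Pol lineage cluster by best local alignment score against the
#' panel's Pol references. When the two best clusters are the early
#' bat cluster and the divergent microbat cluster within `margin` of each
#' other the proxy is `BAT_AMBIG` (the alignment proxy cannot separate the
#' two bat lineages; tree topology would be needed).
#'
#' @param pol_translation pol protein.
#' @param pol_refs named character vector of Pol cluster references.
#' @param margin relative margin for the bat-cluster ambiguity rule.
#' @param params alignment parameters.
#' @return list: `cluster` (reference name, `BAT_AMBIG` or `unknown`),
#'   `scores` (named numeric).
#' @export
phylo_proxy <- function(pol_translation, pol_refs, margin = 0.02,
                        params = alignment_params(low_complexity_filter = FALSE)) {
  scores <- vapply(pol_refs, function(r)
    as.numeric(local_align_protein(r, pol_translation, params,
                                   score_only = TRUE)$score), 1)
  if (max(scores) < 50) return(list(cluster = "unknown", scores = scores))
  ord <- order(-scores)
  top <- names(scores)[ord[1]]; second <- names(scores)[ord[2]]
  if (all(c("BAT_EARLY", "MICROBAT_DIV") %in% c(top, second)) &&
      scores[ord[1]] - scores[ord[2]] < margin * scores[ord[1]]) {
    return(list(cluster = "BAT_AMBIG", scores = scores))
  }
  list(cluster = top, scores = scores)
}

#' Classification feature vector
#'
#' @param pbs_type one of Lys1_2, Lys3, LysAlt, unknown.
#' @param ltr_len LTR length in nt (NA allowed), mapped to the class
#'   short (<= 600), long (>= 1000) or unknown.
#' @param env one of beta, gamma, unknown.
#' @param extra_orf_placements character vector of extra-ORF placements
#'   (subset of pre-gag, within-core-alt-frame, post-env, in-LTR).
#' @param dutpase_present logical.
#' @param proxy Pol placement proxy cluster name.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(pbs_type = "unknown", ltr_len = NA,
                           env = "unknown",
                           extra_orf_placements = character(0),
                           dutpase_present = NA, proxy = "unknown") {
  ltr_class <- if (is.na(ltr_len)) "unknown"
  else if (ltr_len <= 600) "short"
  else if (ltr_len >= 1000) "long"
  else "unknown"
  structure(list(pbs_type = pbs_type, ltr_class = ltr_class,
                 ltr_len = ltr_len, env_lineage = env,
                 extra_orf_placements = extra_orf_placements,
                 dutpase_present = dutpase_present, phylo_proxy = proxy),
            class = "feature_vector")
}

#' Assign a provirus to one of the eight betaretroviral sub-groups
#'
#' Ordered decision rules over the feature vector:
#' \itemize{
#'   \item a gammaretroviral env dominates everything: group VIII (a
#'     conflicting feature such as a long LTR is noted in the trace);
#'   \item Pol proxy HERVK + Lys1_2 PBS: group I;
#'   \item Pol proxy in the early-branching bat cluster: group II;
#'   \item divergent-Pol microbat cluster + Lys3: group III;
#'   \item LysAlt PBS + Type B Pol: group IV;
#'   \item long LTR (~1200 nt) + Lys3 + Type B Pol: group V;
#'   \item short LTR + Lys1_2 + beta env: group VI;
#'   \item short LTR + Lys3 + beta env: group VII;
#'   \item otherwise unclassified.
#' }
#' When the Pol proxy is `BAT_AMBIG` the label is "II-or-III" rather than a
#' guess between the two bat clusters.
#'
#' @param features a [feature_vector()].
#' @return list of class `group_label`: `group` ("I".."VIII",
#'   "II-or-III" or "unclassified") and `trace` (ordered rules fired).
#' @export
classify_group <- function(features) {
  stopifnot(inherits(features, "feature_vector"))
  f <- features
  trace <- character(0)
  lab <- function(group, trace) {
    structure(list(group = group, trace = trace), class = "group_label")
  }
  if (identical(f$env_lineage, "gamma")) {
    trace <- c(trace, "env=gamma -> VIII (dominant rule)")
    if (identical(f$ltr_class, "long"))
      trace <- c(trace, "warning: long LTR conflicts with gamma env")
    return(lab("VIII", trace))
  }
  if (identical(f$phylo_proxy, "BAT_AMBIG")) {
    return(lab("II-or-III",
               "pol proxy cannot separate the bat clusters (II vs III)"))
  }
  if (identical(f$phylo_proxy, "HERVK") && identical(f$pbs_type, "Lys1_2"))
    return(lab("I", "pol proxy HERVK + PBS Lys1_2 -> I"))
  if (identical(f$phylo_proxy, "BAT_EARLY"))
    return(lab("II", "pol proxy early bat cluster -> II"))
  if (identical(f$phylo_proxy, "MICROBAT_DIV") &&
      identical(f$pbs_type, "Lys3"))
    return(lab("III", "divergent microbat pol + PBS Lys3 -> III"))
  if (identical(f$pbs_type, "LysAlt") && identical(f$phylo_proxy, "TYPE_B"))
    return(lab("IV", "PBS LysAlt + Type B pol -> IV"))
  if (identical(f$ltr_class, "long") && identical(f$pbs_type, "Lys3") &&
      identical(f$phylo_proxy, "TYPE_B"))
    return(lab("V", "long LTR + PBS Lys3 + Type B pol -> V"))
  if (identical(f$ltr_class, "short") && identical(f$pbs_type, "Lys1_2") &&
      identical(f$env_lineage, "beta"))
    return(lab("VI", "short LTR + PBS Lys1_2 + beta env -> VI"))
  if (identical(f$ltr_class, "short") && identical(f$pbs_type, "Lys3") &&
      identical(f$env_lineage, "beta"))
    return(lab("VII", "short LTR + PBS Lys3 + beta env -> VII"))
  lab("unclassified", character(0))
}

#' @export
print.group_label <- function(x, ...) {
  cat("<group_label>", x$group, "\n")
  for (t in x$trace) cat("  ", t, "\n")
  invisible(x)
}

#' Canonical feature vectors, one per sub-group representative
#'
#' The eight representatives' features (PBS class, LTR class, env lineage,
#' characteristic extra ORFs, Pol placement) as used to define the
#' sub-groups; classifying them yields eight distinct labels.
#'
#' @return named list of [feature_vector()] objects.
#' @export
canonical_feature_vectors <- function() {
  list(
    I = feature_vector("Lys1_2", 968, "beta", character(0), TRUE, "HERVK"),
    II = feature_vector("Lys1_2", 422, "beta", "in-LTR", TRUE, "BAT_EARLY"),
    III = feature_vector("Lys3", 479, "beta", character(0), TRUE,
                         "MICROBAT_DIV"),
    IV = feature_vector("LysAlt", 500, "beta", character(0), TRUE, "TYPE_B"),
    V = feature_vector("Lys3", 1265, "beta", "in-LTR", TRUE, "TYPE_B"),
    VI = feature_vector("Lys1_2", 398, "beta", "within-core-alt-frame",
                        TRUE, "TYPE_D"),
    VII = feature_vector("Lys3", 370, "beta", "pre-gag", TRUE, "TYPE_D"),
    VIII = feature_vector("Lys1_2", 427, "gamma", "post-env", TRUE, "TYPE_D")
  )
}
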