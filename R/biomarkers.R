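#' CSF and MRI biomarker cutoffs
#'
#' Positivity conventions follow each printed clinical inequality literally:
#' amyloid positivity (A+) is strict `abeta42 < abeta_pos_below`; tau (T+) and
#' neurodegeneration (N+) positivity are strict `>`; vascular positivity (V+)
#' is `fazekas >= fazekas_vpos_at_least` or `cmb_count >= cmb_vpos_at_least`.
#'
#' The default amyloid threshold is the operationally adjusted 580 pg/mL
#' (the assay-derived 550 pg/mL cutoff widened by a 5% confidence margin);
#' pass `abeta_pos_below = 550` to use the unadjusted value.
#'
#' @param abeta_pos_below CSF amyloid-beta 42 threshold, pg/mL.
#' @param ptau_pos_above CSF phosphorylated-tau threshold, pg/mL.
#' @param ttau_pos_above CSF total-tau threshold, pg/mL.
#' @param fazekas_vpos_at_least Fazekas white-matter-hyperintensity score (0-3)
#'   defining severe WMH.
#' @param cmb_vpos_at_least Cerebral microbleed count defining high burden.
#' @return An object of class `biomarker_cutoffs`.
#' @export
biomarker_cutoffs <- function(abeta_pos_below = 580, ptau_pos_above = 61,
                              ttau_pos_above = 350, fazekas_vpos_at_least = 2L,
                              cmb_vpos_at_least = 4L) {
  vals <- c(abeta_pos_below, ptau_pos_above, ttau_pos_above,
            fazekas_vpos_at_least, cmb_vpos_at_least)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cutoffs must be positive finite numbers", call. = FALSE)
  }
  structure(
    list(abeta_pos_below = abeta_pos_below, ptau_pos_above = ptau_pos_above,
         ttau_pos_above = ttau_pos_above,
         fazekas_vpos_at_least = fazekas_vpos_at_least,
         cmb_vpos_at_least = cmb_vpos_at_least),
    class = "biomarker_cutoffs"
  )
}

#' @export
print.biomarker_cutoffs <- function(x, ...) {
  cat(sprintf(paste0("Biomarker cutoffs: A+ if abeta42 < %g pg/mL; T+ if p-tau > %g;",
                     " N+ if t-tau > %g; V+ if Fazekas >= %d or CMB >= %d\n"),
              x$abeta_pos_below, x$ptau_pos_above, x$ttau_pos_above,
              x$fazekas_vpos_at_least, x$cmb_vpos_at_least))
  invisible(x)
}

#' AT(N) status from CSF markers
#'
#' Vectorized over participants. A marker missing in a row yields `NA` for
#' that axis, which propagates to an `unclassifiable` group label.
#'
#' @param abeta42,ptau,ttau Numeric vectors of CSF concentrations (pg/mL).
#' @param cutoffs A [biomarker_cutoffs()] object.
#' @return A tibble with character columns `A`, `T`, `N` holding `"+"`/`"-"`
#'   (or `NA` where the marker is missing).
#' @export
atn_status <- function(abeta42, ptau, ttau, cutoffs = biomarker_cutoffs()) {
  stopifnot(inherits(cutoffs, "biomarker_cutoffs"))
  pm <- function(x) ifelse(x, "+", "-")
  tibble::tibble(
    A = pm(abeta42 < cutoffs$abeta_pos_below),
    T = pm(ptau > cutoffs$ptau_pos_above),
    N = pm(ttau > cutoffs$ttau_pos_above)
  )
}

#' Cerebrovascular burden status from MRI ratings
#'
#' V+ if the Fazekas score reaches the severe-WMH threshold or the microbleed
#' count reaches the high-burden threshold. If one rating is missing the other
#' can still establish positivity; a row is `NA` only when neither rating
#' decides.
#'
#' @param fazekas Integer vector, Fazekas scores 0-3.
#' @param cmb_count Integer vector, cerebral microbleed counts.
#' @param cutoffs A [biomarker_cutoffs()] object.
#' @return Character vector of `"+"`/`"-"` (or `NA`).
#' @export
vascular_status <- function(fazekas, cmb_count, cutoffs = biomarker_cutoffs()) {
  stopifnot(inherits(cutoffs, "biomarker_cutoffs"))
  faz_pos <- fazekas >= cutoffs$fazekas_vpos_at_least
  cmb_pos <- cmb_count >= cutoffs$cmb_vpos_at_least
  pos <- (!is.na(faz_pos) & faz_pos) | (!is.na(cmb_pos) & cmb_pos)
  neg <- (!is.na(faz_pos) & !faz_pos) & (!is.na(cmb_pos) & !cmb_pos)
  ifelse(pos, "+", ifelse(neg, "-", NA_character_))
}

#' Assign analysis-group labels from biomarker status
#'
#' Three mutually exclusive analysis groups:
#' * `CUA-V-` — biomarker negative: A-T-N- and V-;
#' * `CUA+`  — amyloid pathology: A+ (irrespective of T and N) and V-;
#' * `CUV+`  — vascular pathology: V+ with an otherwise negative AT(N)
#'   profile (A-T-N-).
#'
#' Profiles fitting none of the three (e.g. A+V+, or isolated T+/N+) are
#' labelled `other`; rows whose status cannot be established, or flagged for
#' cortical superficial siderosis / established ischemic lesions, are
#' `unclassifiable` and `other` respectively.
#'
#' @param A,T,N Character vectors of `"+"`/`"-"` from [atn_status()].
#' @param V Character vector from [vascular_status()].
#' @param exclude Optional logical vector; `TRUE` forces the label `other`
#'   (lesion-based exclusion, not a vascular-positivity contribution).
#' @return Character vector of group labels.
#' @export
assign_group <- function(A, T, N, V, exclude = NULL) {
  atn_neg <- A == "-" & T == "-" & N == "-"
  lab <- ifelse(is.na(A) | is.na(T) | is.na(N) | is.na(V), "unclassifiable",
         ifelse(atn_neg & V == "-", "CUA-V-",
         ifelse(A == "+" & V == "-", "CUA+",
         ifelse(atn_neg & V == "+", "CUV+", "other"))))
  if (!is.null(exclude)) {
    lab <- ifelse(!is.na(exclude) & exclude & lab != "unclassifiable", "other", lab)
  }
  lab
}

#' Classify every row of a participant table
#'
#' Convenience wrapper that runs [atn_status()], [vascular_status()] and
#' [assign_group()] on the table's biomarker columns and appends the results.
#'
#' @param table Participant table with columns `abeta42`, `ptau`, `ttau`,
#'   `fazekas`, `cmb_count`, and optionally `css` / `ischemic_lesion` flags.
#' @param cutoffs A [biomarker_cutoffs()] object.
#' @return The table with added columns `A`, `T`, `N`, `V` and `group`
#'   (overwriting any existing `group` column).
#' @export
classify_cohort <- function(table, cutoffs = biomarker_cutoffs()) {
  need <- c("abeta42", "ptau", "ttau", "fazekas", "cmb_count")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("missing biomarker column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  atn <- atn_status(table$abeta42, table$ptau, table$ttau, cutoffs)
  V <- vascular_status(table$fazekas, table$cmb_count, cutoffs)
  excl <- rep(FALSE, nrow(table))
  for (col in c("css", "ischemic_lesion")) {
    if (col %in% names(table)) excl <- excl | (!is.na(table[[col]]) & table[[col]])
  }
  table$A <- atn$A; table$T <- atn$T; table$N <- atn$N; table$V <- V
  table$group <- assign_group(atn$A, atn$T, atn$N, V, exclude = excl)
  table
}
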