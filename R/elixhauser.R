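# The embedded table is the enhanced ICD-9-CM Elixhauser coding algorithm of
# Quan et al. (2005), the lineage used by the MIMIC community scripts.
# Matching is by code prefix on dot-free, uppercased codes: a table prefix
# matches any code that starts with it, which tolerates 4- vs 5-digit coding.

# Quan et al. 2005 enhanced ICD-9-CM Elixhauser prefixes, one entry per
# category, hypertension kept as separate uncomplicated/complicated flags
# (31 categories; a switch below merges them into 30).
quan2005_prefixes <- function() {
  list(
    chf = c("39891", "40201", "40211", "40291", "40401", "40403", "40411",
            "40413", "40491", "40493", "4254", "4255", "4256", "4257",
            "4258", "4259", "428"),
    arrhythmia = c("4260", "42613", "4267", "4269", "42610", "42612",
                   "4270", "4271", "4272", "4273", "4274", "4276", "4277",
                   "4278", "4279", "7850", "99601", "99604", "V450", "V533"),
    valvular = c("0932", "394", "395", "396", "397", "424", "7463", "7464",
                 "7465", "7466", "V422", "V433"),
    pulm_circ = c("4150", "4151", "416", "4170", "4178", "4179"),
    pvd = c("0930", "4373", "440", "441", "4431", "4432", "4433", "4434",
            "4435", "4436", "4437", "4438", "4439", "4471", "5571", "5579",
            "V434"),
    htn_uncomp = "401",
    htn_comp = c("402", "403", "404", "405"),
    paralysis = c("3341", "342", "343", "3440", "3441", "3442", "3443",
                  "3444", "3445", "3446", "3449"),
    neuro_other = c("3319", "3320", "3321", "3334", "3335", "33392", "334",
                    "335", "3362", "340", "341", "345", "3481", "3483",
                    "7803", "7843"),
    chronic_pulm = c("4168", "4169", sprintf("%03d", 490:505), "5064",
                     "5081", "5088"),
    dm_uncomp = c("2500", "2501", "2502", "2503"),
    dm_comp = c("2504", "2505", "2506", "2507", "2508", "2509"),
    hypothyroid = c("2409", "243", "244", "2461", "2468"),
    renal_failure = c("40301", "40311", "40391", "40402", "40403", "40412",
                      "40413", "40492", "40493", "585", "586", "5880",
                      "V420", "V451", "V56"),
    liver = c("07022", "07023", "07032", "07033", "07044", "07054", "0706",
              "0709", "4560", "4561", "4562", "570", "571", "5722", "5723",
              "5724", "5725", "5726", "5727", "5728", "5733", "5734",
              "5738", "5739", "V427"),
    pud = c("5317", "5319", "5327", "5329", "5337", "5339", "5347", "5349"),
    aids_hiv = c("042", "043", "044"),
    lymphoma = c("200", "201", "202", "2030", "2386"),
    mets = c("196", "197", "198", "199"),
    solid_tumor = sprintf("%03d", c(140:172, 174:195)),
    rheum = c("446", "7010", "7100", "7101", "7102", "7103", "7104", "7108",
              "7109", "7112", "714", "7193", "720", "725", "7285", "72889",
              "72930"),
    coag = c("286", "2871", "2873", "2874", "2875"),
    obesity = "2780",
    weight_loss = c("260", "261", "262", "263", "7832", "7994"),
    fluid_electrolyte = c("2536", "276"),
    blood_loss_anemia = "2800",
    def_anemia = c("2801", "2802", "2803", "2804", "2805", "2806", "2807",
                   "2808", "2809", "281"),
    alcohol = c("2652", "2911", "2912", "2913", "2915", "2916", "2917",
                "2918", "2919", "3030", "3039", "3050", "3575", "4255",
                "5353", "5710", "5711", "5712", "5713", "980", "V113"),
    drug = c("292", "304", "3052", "3053", "3054", "3055", "3056", "3057",
             "3058", "3059", "V6542"),
    psychoses = c("2938", "295", "29604", "29614", "29644", "29654", "297",
                  "298"),
    depression = c("2962", "2963", "2965", "311")
  )
}

#' Load an Elixhauser comorbidity mapping
#'
#' Returns the ordered category-to-ICD-9-prefix table used to flag chronic
#' conditions. The only embedded dialect is `"quan2005"` (enhanced ICD-9-CM).
#'
#' @param dialect name of the embedded mapping table.
#' @param combine_hypertension if `TRUE`, merge the uncomplicated and
#'   complicated hypertension flags into a single `htn` category (30
#'   categories); the default keeps them separate (31).
#' @return An object of class `elixhauser_map`: a named list of character
#'   prefix vectors in stable category order, with a `dialect` attribute.
#' @examples
#' m <- elixhauser_map()
#' length(m)                     # 31
#' length(elixhauser_map(combine_hypertension = TRUE))  # 30
#' @export
elixhauser_map <- function(dialect = "quan2005", combine_hypertension = FALSE) {
  known <- c("quan2005")
  if (!dialect %in% known)
    stop(sprintf("unknown Elixhauser dialect '%s'; available: %s",
                 dialect, paste(known, collapse = ", ")))
  prefixes <- quan2005_prefixes()
  if (combine_hypertension) {
    htn <- union(prefixes$htn_uncomp, prefixes$htn_comp)
    idx <- match("htn_uncomp", names(prefixes))
    prefixes <- prefixes[setdiff(names(prefixes), c("htn_uncomp", "htn_comp"))]
    prefixes <- append(prefixes, list(htn = htn), after = idx - 1L)
  }
  structure(prefixes, class = "elixhauser_map", dialect = dialect,
            combine_hypertension = combine_hypertension)
}

#' @export
print.elixhauser_map <- function(x, ...) {
  cat(sprintf("Elixhauser mapping (%s): %d categories, %d ICD-9 prefixes\n",
              attr(x, "dialect"), length(x), sum(lengths(x))))
  invisible(x)
}

#' Normalize ICD-9 codes
#'
#' Strips dots and whitespace and uppercases, the form the embedded prefix
#' table uses.
#'
#' @param codes character vector of ICD-9-CM codes.
#' @return normalized character vector.
#' @export
normalize_icd9 <- function(codes) {
  toupper(gsub("[. ]", "", as.character(codes)))
}

#' Map ICD-9 codes to comorbidity flags
#'
#' Sets flag *j* to 1 when any code has a prefix listed under category *j*.
#' One code may set several categories (e.g. `40391` flags both complicated
#' hypertension and renal failure). Unmatched codes are ignored; their count
#' is attached as the `n_unmatched` attribute.
#'
#' @param codes character vector of ICD-9-CM codes (dots allowed).
#' @param mapping an [elixhauser_map()].
#' @return named integer 0/1 vector, one entry per category.
#' @examples
#' m <- elixhauser_map()
#' map_codes("401.9", m)["htn_uncomp"]
#' @export
map_codes <- function(codes, mapping = elixhauser_map()) {
  codes <- normalize_icd9(codes)
  codes <- codes[nzchar(codes)]
  flags <- vapply(mapping, function(pref) {
    as.integer(any(vapply(codes, function(cd) any(startsWith(cd, pref)),
                          logical(1))))
  }, integer(1))
  if (length(codes)) {
    matched <- vapply(codes, function(cd)
      any(vapply(mapping, function(pref) any(startsWith(cd, pref)),
                 logical(1))), logical(1))
    attr(flags, "n_unmatched") <- sum(!matched)
  } else attr(flags, "n_unmatched") <- 0L
  flags
}

#' Build the patient-by-category comorbidity matrix
#'
#' @param patients patient table with a `patient_id` column and an `icd9`
#'   column holding semicolon-joined diagnosis codes (empty string for none).
#' @param mapping an [elixhauser_map()].
#' @return binary matrix, rows named by patient id, columns by category; the
#'   total number of unmatched codes is attached as `n_unmatched`.
#' @export
comorbidity_matrix <- function(patients, mapping = elixhauser_map()) {
  code_lists <- strsplit(as.character(patients$icd9), ";", fixed = TRUE)
  rows <- lapply(code_lists, map_codes, mapping = mapping)
  x <- do.call(rbind, rows)
  rownames(x) <- patients$patient_id
  structure(x, n_unmatched = sum(vapply(rows, attr, integer(1),
                                        "n_unmatched")))
}

#' Default TBI ICD-9 prefix set
#'
#' Dot-free prefixes covering skull fracture (800-801, 803-804), intracranial
#' injury (850-854), late effects (9501-9503) and head injury unspecified
#' (95901) -- the CDC-style surveillance definition of traumatic brain injury.
#'
#' @return character vector of prefixes.
#' @export
tbi_code_prefixes <- function() {
  c("800", "801", "803", "804", "850", "851", "852", "853", "854",
    "9501", "9502", "9503", "95901")
}

#' Restrict an admissions table to first TBI admissions
#'
#' Keeps admissions carrying at least one diagnosis code matching a TBI
#' prefix; among a patient's qualifying admissions only the earliest by
#' admission date survives (date ties broken by the lexicographically
#' smallest `admission_id`). The result has one row per patient.
#'
#' @param admissions data frame with `patient_id`, `admit_date` (parseable as
#'   `Date`), `icd9` (semicolon-joined codes) and optionally `admission_id`.
#' @param tbi_codes character vector of dot-free ICD-9 prefixes defining the
#'   index condition.
#' @return the filtered admissions table (same columns, unique patient ids).
#' @export
filter_cohort <- function(admissions, tbi_codes = tbi_code_prefixes()) {
  stopifnot(length(tbi_codes) > 0)
  codes <- strsplit(normalize_icd9(admissions$icd9), ";", fixed = TRUE)
  has_tbi <- vapply(codes, function(cs)
    any(vapply(cs, function(cd) any(startsWith(cd, tbi_codes)), logical(1))),
    logical(1))
  kept <- admissions[has_tbi, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no admissions match the TBI code prefixes")
    return(kept)
  }
  adm_id <- if ("admission_id" %in% names(kept)) as.character(kept$admission_id)
            else as.character(seq_len(nrow(kept)))
  ord <- order(as.character(kept$patient_id), as.Date(kept$admit_date), adm_id)
  kept <- kept[ord, , drop = FALSE]
  first <- !duplicated(kept$patient_id)
  out <- kept[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin Glasgow Coma Scale scores into severity categories
#'
#' mild = GCS 14-15, moderate = 9-13, severe = 3-8.
#'
#' @param gcs integer vector in 3..15; `NA` passes through as `NA`.
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @export
bin_gcs <- function(gcs) {
  ok <- is.na(gcs) | (gcs >= 3 & gcs <= 15)
  if (!all(ok))
    stop("GCS values must lie in 3..15 (or be missing)")
  out <- ifelse(is.na(gcs), NA_character_,
         ifelse(gcs >= 14, "mild", ifelse(gcs >= 9, "moderate", "severe")))
  factor(out, levels = c("mild", "moderate", "severe"))
}

#' Bin age into cohort age groups
#'
#' young = 16-39, middle-aged = 40-69, old = 70 and above.
#'
#' @param age numeric vector of ages in years, all at least 16.
#' @return factor with levels `young`, `middle-aged`, `old`.
#' @export
bin_age <- function(age) {
  if (any(age < 16, na.rm = TRUE))
    stop("ages below 16 are outside the adult cohort definition")
  out <- ifelse(is.na(age), NA_character_,
         ifelse(age < 40, "young", ifelse(age < 70, "middle-aged", "old")))
  factor(out, levels = c("young", "middle-aged", "old"))
}
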