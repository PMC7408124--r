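#' @importFrom utils write.csv read.csv
NULL

# Closed substituent vocabulary. Fragments are written as SMILES branches;
# aryl ring-closure digits start at 3 because the scaffold uses 1 and 2.
.position3_groups <- c(
  acetyl          = "C(C)=O",
  methoxycarbonyl = "C(=O)OC",
  ethoxycarbonyl  = "C(=O)OCC",
  cyano           = "C#N",
  benzoyl         = "C(=O)c3ccccc3",
  none            = ""
)
.ring_groups <- c(
  hydroxy        = "O",
  methoxy        = "OC",
  ethoxy         = "OCC",
  bromo          = "Br",
  chloro         = "Cl",
  benzyloxy      = "OCc3ccccc3",
  benzoyl        = "C(=O)c3ccccc3",
  diethylamino   = "N(CC)CC",
  dihydroxyamino = "N(O)O",
  none           = ""
)

#' Substituent specification for the coumarin scaffold
#'
#' Describes one compound as a 2H-chromen-2-one (coumarin) core decorated at
#' position 3 and at the benzo-ring positions 6, 7 and 8 (standard coumarin
#' numbering: O1, C2=O, C3, C4, C4a, C5-C8, C8a). Group names come from a
#' closed vocabulary; plain coumarin is the all-`"none"` spec.
#'
#' @param position_3 group at C3: one of `"acetyl"`, `"methoxycarbonyl"`,
#'   `"ethoxycarbonyl"`, `"cyano"`, `"benzoyl"`, `"none"`.
#' @param ring_subs named character vector mapping ring position (`"6"`,
#'   `"7"`, `"8"`) to a group name from the ring vocabulary.
#' @return an object of class `substituent_spec`.
#' @examples
#' substituent_spec("benzoyl", c("7" = "benzyloxy"))  # the strongest inhibitor
#' @export
substituent_spec <- function(position_3 = "none", ring_subs = character(0)) {
  if (!position_3 %in% names(.position3_groups)) {
    stop("unknown position-3 group: '", position_3, "'")
  }
  if (length(ring_subs)) {
    if (is.null(names(ring_subs)) || !all(names(ring_subs) %in% c("6", "7", "8"))) {
      stop("ring substituent positions must be named 6, 7 or 8")
    }
    bad <- setdiff(ring_subs, names(.ring_groups))
    if (length(bad)) stop("unknown ring group: '", bad[1], "'")
  }
  structure(list(position_3 = position_3, ring_subs = ring_subs),
            class = "substituent_spec")
}

#' Build the SMILES of a substituted coumarin
#'
#' Assembles a Kekule SMILES of the 2H-chromen-2-one scaffold carrying the
#' groups of a [substituent_spec()] at the numbered positions. The benzo
#' ring is written aromatic; the pyranone ring is written with explicit
#' bond orders.
#'
#' @param spec a [substituent_spec()].
#' @return a single SMILES string.
#' @examples
#' smiles_from_spec(substituent_spec())                 # coumarin, C9H6O2
#' smiles_from_spec(substituent_spec("acetyl"))         # C11H8O3
#' @export
smiles_from_spec <- function(spec) {
  stopifnot(inherits(spec, "substituent_spec"))
  frag <- function(tab, g) if (g == "none" || g == "") "" else paste0("(", tab[[g]], ")")
  g3 <- frag(.position3_groups, spec$position_3)
  rs <- function(pos) {
    g <- if (pos %in% names(spec$ring_subs)) spec$ring_subs[[pos]] else "none"
    frag(.ring_groups, g)
  }
  # ring walk: C4a, C5, C6, C7, C8, C8a (C8a closes onto O1)
  paste0("O=C1C", g3, "=Cc2c", "c", rs("6"), "c", rs("7"), "c", rs("8"), "c2O1")
}

# Table of the analysed compound set: identifiers, substituent pattern,
# measured activities (percent at 100 uM), the published log response and
# the published calculated response. Compounds 38/39 have no lipoxygenase
# value (cloudy reaction mixture); compound 14 is the published training-set
# outlier of the final model.
.compound_rows <- list(
  #     no  id     pos3               ring subs                         dpph   lp    lox   ic50   log   calc
  list( 1, "A1",  "acetyl",          c(),                               16.3, 23.0, 18.5,    NA, 1.27, 1.11),
  list( 2, "A2",  "methoxycarbonyl", c(),                               32.1, 16.6,  7.1,    NA, 0.85, 1.04),
  list( 3, "A3",  "ethoxycarbonyl",  c(),                               33.5,  7.0, 14.3,    NA, 1.15, 1.09),
  list( 4, "A4",  "cyano",           c(),                               36.4,   NA, 14.8,    NA, 1.17, 1.37),
  list( 5, "A5",  "benzoyl",         c(),                               31.1, 42.1, 22.5,    NA, 1.35, 1.31),
  list( 6, "C4",  "cyano",           c("7" = "benzoyl"),                32.1, 57.9, 33.9,    NA, 1.53, 1.73),
  list( 7, "C5",  "benzoyl",         c("7" = "benzyloxy"),              36.3, 86.1, 96.6, 26.82, 1.98, 1.97),
  list( 8, "COUM","none",            c(),                               33.2,  2.6, 23.1,    NA, 1.36, 1.31),
  list( 9, "D1",  "acetyl",          c("8" = "hydroxy"),                25.2, 38.0, 29.3,    NA, 1.47, 1.49),
  list(10, "D4",  "cyano",           c("8" = "hydroxy"),                39.2, 12.9, 39.5,    NA, 1.60, 1.74),
  list(11, "E1",  "acetyl",          c("7" = "hydroxy"),                15.9, 29.8, 45.1,    NA, 1.65, 1.57),
  list(12, "E2",  "methoxycarbonyl", c("7" = "hydroxy"),                15.2, 44.7, 37.4,    NA, 1.57, 1.51),
  list(13, "E5",  "benzoyl",         c("7" = "hydroxy"),                32.7, 55.2, 76.1, 13.98, 1.88, 1.79),
  list(14, "F1",  "acetyl",          c("7" = "diethylamino"),           16.4, 41.6, 16.8,    NA, 1.22,   NA),
  list(15, "G1",  "acetyl",          c("6" = "bromo"),                  21.2, 70.6, 11.3,    NA, 1.05, 1.18),
  list(16, "G2",  "methoxycarbonyl", c("6" = "bromo"),                  28.4, 86.6, 85.1, 61.00, 1.93, 1.40),
  list(17, "G3",  "ethoxycarbonyl",  c("6" = "bromo"),                  32.9, 76.7, 55.2, 97.48, 1.74, 1.45),
  list(18, "G4",  "cyano",           c("6" = "bromo"),                  48.4, 81.0, 84.8, 64.77, 1.93, 1.77),
  list(19, "J1",  "acetyl",          c("6" = "hydroxy"),                22.5, 69.2, 48.5,    NA, 1.69, 1.53),
  list(20, "J2",  "methoxycarbonyl", c("6" = "hydroxy"),                24.0, 62.8, 25.4,    NA, 1.40, 1.49),
  list(21, "J3",  "ethoxycarbonyl",  c("6" = "hydroxy"),                58.1, 47.1, 51.9, 17.40, 1.71, 1.54),
  list(22, "J4",  "cyano",           c("6" = "hydroxy"),                39.0, 66.8, 29.3,    NA, 1.47, 1.77),
  list(23, "J5",  "benzoyl",         c("6" = "hydroxy"),                38.9, 66.5, 55.4, 88.55, 1.74, 1.77),
  list(24, "K3",  "ethoxycarbonyl",  c("6" = "chloro"),                 31.2, 64.4, 47.6,    NA, 1.68, 1.47),
  list(25, "K5",  "benzoyl",         c("6" = "chloro"),                 32.1, 58.1, 37.0,    NA, 1.57, 1.69),
  list(26, "L3",  "ethoxycarbonyl",  c("6" = "bromo", "8" = "bromo"),   31.7, 31.1, 56.1, 84.35, 1.75, 1.81),
  list(27, "M2",  "methoxycarbonyl", c("7" = "methoxy"),                21.0, 61.9, 25.2,    NA, 1.40, 1.56),
  list(28, "M3",  "ethoxycarbonyl",  c("7" = "methoxy"),                32.9, 91.0, 36.5,    NA, 1.56, 1.59),
  list(29, "M4",  "cyano",           c("7" = "methoxy"),                35.0, 57.5, 34.8,    NA, 1.54, 1.62),
  list(30, "N2",  "methoxycarbonyl", c("6" = "methoxy"),                20.5, 75.3, 76.0, 52.54, 1.88, 1.53),
  list(31, "N4",  "cyano",           c("6" = "methoxy"),                14.9, 84.4, 37.8,    NA, 1.58, 1.58),
  list(32, "O1",  "acetyl",          c("8" = "ethoxy"),                 19.6, 36.1, 18.0,    NA, 1.26, 1.55),
  list(33, "O3",  "ethoxycarbonyl",  c("8" = "ethoxy"),                 36.0, 19.1, 21.9,    NA, 1.34, 1.53),
  list(34, "O4",  "cyano",           c("8" = "ethoxy"),                 16.3, 16.9, 52.9, 96.42, 1.72, 1.56),
  list(35, "O5",  "benzoyl",         c("8" = "ethoxy"),                 29.7, 66.3, 26.1,    NA, 1.42, 1.70),
  list(36, "P2",  "methoxycarbonyl", c("6" = "dihydroxyamino"),         22.9, 29.7, 40.5,    NA, 1.61, 1.53),
  list(37, "P3",  "ethoxycarbonyl",  c("6" = "dihydroxyamino"),         33.1, 29.1, 46.6,    NA, 1.67, 1.61),
  list(38, "L5",  "benzoyl",         c("6" = "bromo", "8" = "bromo"),   35.7, 73.0,   NA,    NA,   NA,   NA),
  list(39, "M5",  "benzoyl",         c("7" = "methoxy"),                29.3, 69.2,   NA,    NA,   NA,   NA)
)

.published_test_ids <- c(16L, 19L, 22L, 24L, 25L, 28L, 35L, 37L)
.published_outlier_id <- 14L

#' The coumarin lipoxygenase data set
#'
#' Returns the 39-compound table of substituted coumarins with their
#' measured activities: DPPH radical scavenging, inhibition of linoleic
#' acid lipid peroxidation, and soybean lipoxygenase inhibition, all in
#' percent at 100 uM, plus the base-10 log of the lipoxygenase percentage
#' as published and the published model's calculated response. SMILES are
#' rebuilt from the substituent specifications. The published train/test
#' split is applied: compounds 16, 19, 22, 24, 25, 28, 35 and 37 form the
#' external test set, compounds 38 and 39 carry no lipoxygenase value and
#' are excluded from modelling, and compound 14 is flagged as the
#' training-set outlier removed from the final model.
#'
#' @return a data frame of class `coumarin_set` with one row per compound
#'   and a `spec` list-column of [substituent_spec()] objects.
#' @examples
#' tbl <- coumarin_table()
#' subset(tbl, split == "test")$no
#' @export
coumarin_table <- function() {
  rows <- lapply(.compound_rows, function(r) {
    spec <- substituent_spec(r[[3]], unlist(r[[4]]))
    data.frame(
      no = as.integer(r[[1]]), mol_id = r[[2]],
      substituents = format_spec(spec),
      smiles = smiles_from_spec(spec),
      dpph_pct = r[[5]], lp_pct = r[[6]], lox_pct = r[[7]],
      ic50_um = r[[8]], log_lox = r[[9]], calc_eq2 = r[[10]],
      stringsAsFactors = FALSE
    )
  })
  tbl <- do.call(rbind, rows)
  tbl$split <- ifelse(is.na(tbl$lox_pct), "excluded",
                      ifelse(tbl$no %in% .published_test_ids, "test", "train"))
  tbl$outlier <- tbl$no == .published_outlier_id
  tbl$spec <- lapply(.compound_rows, function(r) substituent_spec(r[[3]], unlist(r[[4]])))
  class(tbl) <- c("coumarin_set", "data.frame")
  tbl
}

format_spec <- function(spec) {
  parts <- character(0)
  if (spec$position_3 != "none") parts <- paste0("3-", spec$position_3)
  for (pos in names(spec$ring_subs)) {
    if (spec$ring_subs[[pos]] != "none")
      parts <- c(parts, paste0(pos, "-", spec$ring_subs[[pos]]))
  }
  if (!length(parts)) "" else paste(parts, collapse = "; ")
}

#' Rows of the compound table entering a given model
#'
#' @param tbl a [coumarin_table()].
#' @param model `"eq1"` keeps all 29 published training compounds;
#'   `"eq2"` additionally drops the outlier (compound 14), leaving 28.
#' @param set `"train"`, `"test"` or `"all"` (train + test).
#' @return the selected rows of `tbl`.
#' @export
modeling_rows <- function(tbl, model = c("eq2", "eq1"), set = c("train", "test", "all")) {
  model <- match.arg(model)
  set <- match.arg(set)
  keep <- switch(set,
    train = tbl$split == "train",
    test  = tbl$split == "test",
    all   = tbl$split %in% c("train", "test")
  )
  if (model == "eq2") keep <- keep & !(tbl$outlier & tbl$split == "train")
  tbl[keep, , drop = FALSE]
}

#' Write the compound fixture as CSV and SMILES files
#'
#' @param tbl a [coumarin_table()].
#' @param csv_path,smiles_path output file paths (`NULL` to skip one).
#' @return invisibly, a list of the paths written.
#' @export
write_compound_table <- function(tbl, csv_path = NULL, smiles_path = NULL) {
  flat <- tbl[, setdiff(names(tbl), "spec")]
  if (!is.null(csv_path)) write.csv(flat, csv_path, row.names = FALSE)
  if (!is.null(smiles_path)) {
    writeLines(paste(tbl$smiles, tbl$mol_id), smiles_path)
  }
  invisible(list(csv = csv_path, smiles = smiles_path))
}
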