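#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv
NULL

#' The five odor classes used for aroma aggregation
#'
#' Major floral scent compounds are binned into five odor classes; the class
#' order here fixes the order of `class_percents` vectors everywhere in the
#' package.
#'
#' @return Character vector `c("herbal", "fruity", "cool", "floral", "spicy")`.
#' @export
odor_classes <- function() c("herbal", "fruity", "cool", "floral", "spicy")

#' Construct a GC-MS peak table for one cultivar
#'
#' A peak table holds raw chromatogram peak areas for one flower sample
#' together with the co-analysed internal standard (conventionally
#' 3-heptanone) and the fresh sample weight, i.e. everything needed for
#' internal-standard quantification.
#'
#' @param cultivar_id Sample/cultivar identifier.
#' @param compounds Character vector of compound names (unique).
#' @param peak_areas Non-negative peak areas, same length as `compounds`
#'   (arbitrary area units; only ratios matter).
#' @param is_name Internal standard compound name.
#' @param is_amount Amount of internal standard added, in micrograms.
#' @param is_peak_area Peak area of the internal standard (must be > 0).
#' @param sample_weight Fresh sample weight in grams (must be > 0).
#'
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(cultivar_id, compounds, peak_areas,
                       is_name = "3-heptanone", is_amount, is_peak_area,
                       sample_weight) {
  stopifnot(length(compounds) == length(peak_areas))
  if (!is.numeric(is_peak_area) || length(is_peak_area) != 1 || is.na(is_peak_area) ||
      is_peak_area <= 0) {
    stop("is_peak_area must be a single positive number")
  }
  if (!is.numeric(sample_weight) || length(sample_weight) != 1 || is.na(sample_weight) ||
      sample_weight <= 0) {
    stop("sample_weight must be a single positive number")
  }
  if (!is.numeric(is_amount) || length(is_amount) != 1 || is.na(is_amount) ||
      is_amount <= 0) {
    stop("is_amount must be a single positive number")
  }
  if (anyDuplicated(compounds)) {
    stop("compound names must be unique within a peak table")
  }
  if (any(peak_areas < 0)) stop("peak_areas must be non-negative")
  structure(
    list(cultivar_id = as.character(cultivar_id),
         peaks = setNames(as.numeric(peak_areas), compounds),
         is_name = is_name, is_amount = is_amount,
         is_peak_area = is_peak_area, sample_weight = sample_weight),
    class = "peak_table"
  )
}

#' Quantify volatile contents from a peak table
#'
#' Converts raw GC-MS peak areas into absolute contents by internal-standard
#' ratio:
#' content (ug/g) = (peak area x IS amount / IS peak area) / sample weight,
#' and derives each compound's relative percentage of the total emission.
#'
#' @param table A [peak_table()].
#' @return An object of class `volatile_profile` with elements `cultivar_id`,
#'   `contents` (named, ug/g), `percents` (named, summing to 100 when the
#'   total is positive) and `total` (ug/g).
#' @examples
#' pt <- peak_table("demo", c("linalool", "myrcene"), c(2000, 1000),
#'                  is_amount = 0.5, is_peak_area = 1000, sample_weight = 1.5)
#' quantify_content(pt)
#' @export
quantify_content <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  contents <- (table$peaks * table$is_amount / table$is_peak_area) /
    table$sample_weight
  total <- sum(contents)
  percents <- if (total > 0) 100 * contents / total else contents * 0
  structure(
    list(cultivar_id = table$cultivar_id, contents = contents,
         percents = percents, total = total),
    class = "volatile_profile"
  )
}

#' Select major scent compounds across profiles
#'
#' A compound counts as major when its relative amount strictly exceeds
#' `threshold` percent in at least one profile.
#'
#' @param profiles List of `volatile_profile` objects.
#' @param threshold Percentage threshold in (0, 100]; default 10.
#' @return Sorted character vector of major compound names.
#' @export
select_major_compounds <- function(profiles, threshold = 10) {
  if (length(profiles) == 0) stop("at least one profile is required")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100) {
    stop("threshold must lie in (0, 100]")
  }
  major <- unlist(lapply(profiles, function(p) {
    stopifnot(inherits(p, "volatile_profile"))
    names(p$percents)[p$percents > threshold]
  }))
  sort(unique(major))
}

#' Read an odor-class map
#'
#' The CSV must have columns `compound` and `odor_class`; every class must be
#' one of the five in [odor_classes()]. The package ships an editable default
#' map covering the major lily scent compounds
#' (`system.file("extdata", "odor_map.csv", package = "scentvar")`).
#'
#' @param path CSV path; defaults to the shipped map.
#' @return Named character vector, compound -> odor class.
#' @export
read_odor_map <- function(path = system.file("extdata", "odor_map.csv",
                                             package = "scentvar")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "odor_class") %in% names(df)))
  bad <- setdiff(unique(df$odor_class), odor_classes())
  if (length(bad)) {
    stop("unknown odor class(es): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$compound)) stop("duplicate compounds in odor map")
  setNames(df$odor_class, df$compound)
}

#' Aggregate a volatile profile into odor-class percentages
#'
#' Sums compound percentages within each of the five odor classes. Compounds
#' missing from the odor map contribute to no class; they are reported in the
#' `unmapped` element and raise a warning (an explicit miss, never a silent
#' default).
#'
#' @param profile A `volatile_profile`.
#' @param odor_map Named character vector from [read_odor_map()].
#' @return An object of class `aroma_profile`: `cultivar_id`,
#'   `class_percents` (5-vector in [odor_classes()] order), `unmapped`
#'   (compound names), `unmapped_percent`, `total_content` (ug/g) and `group`
#'   (`NA` until [classify_aroma()] is applied).
#' @export
aggregate_odor_classes <- function(profile, odor_map = read_odor_map()) {
  stopifnot(inherits(profile, "volatile_profile"))
  cls <- odor_classes()
  comps <- names(profile$percents)
  mapped <- comps %in% names(odor_map)
  if (any(!mapped)) {
    warning("compounds without odor-class mapping: ",
            paste(comps[!mapped], collapse = ", "))
  }
  class_percents <- vapply(cls, function(k) {
    sum(profile$percents[mapped][odor_map[comps[mapped]] == k])
  }, numeric(1))
  structure(
    list(cultivar_id = profile$cultivar_id,
         class_percents = class_percents,
         unmapped = comps[!mapped],
         unmapped_percent = sum(profile$percents[!mapped]),
         total_content = profile$total,
         group = NA_character_),
    class = "aroma_profile"
  )
}

#' Build an aroma profile directly from class percentages
#'
#' Convenience constructor for working with published class-percentage tables
#' where per-compound contents are unavailable.
#'
#' @param cultivar_id Identifier.
#' @param class_percents Numeric 5-vector, order herbal, fruity, cool,
#'   floral, spicy.
#' @param total_content Total emission in ug/g (used by the faint rule);
#'   defaults to the class sum so published percent-only rows classify as
#'   scented.
#' @return An `aroma_profile`.
#' @export
aroma_profile <- function(cultivar_id, class_percents,
                          total_content = sum(class_percents)) {
  stopifnot(length(class_percents) == 5, all(class_percents >= -1e-9),
            all(class_percents <= 100 + 1e-9))
  structure(
    list(cultivar_id = as.character(cultivar_id),
         class_percents = setNames(as.numeric(class_percents), odor_classes()),
         unmapped = character(0),
         unmapped_percent = max(0, 100 - sum(class_percents)),
         total_content = total_content,
         group = NA_character_),
    class = "aroma_profile"
  )
}

#' Default aroma-classification decision list
#'
#' An ordered list of rules, each a predicate over the class percentages
#' (`herbal`, `fruity`, `cool`, `floral`, `spicy`) and the `total` emission in
#' ug/g; the first matching rule assigns the group. The defaults are shipped
#' as an editable YAML file
#' (`system.file("extdata", "aroma_rules.yaml", package = "scentvar")`) and
#' approximate the six published lily aroma groups; group membership is not a
#' pure function of the five percentages (sensory assessment and parentage
#' also enter published groupings), so the rules are configuration, not a
#' fixed truth.
#'
#' @param path YAML rule file; defaults to the shipped rules.
#' @return List of rules, each `list(label = , when = )` where `when` is an R
#'   expression string.
#' @export
default_aroma_rules <- function(path = system.file("extdata",
                                                   "aroma_rules.yaml",
                                                   package = "scentvar")) {
  rules <- yaml::read_yaml(path)
  stopifnot(is.list(rules), length(rules) > 0)
  rules
}

.rule_vars <- c(odor_classes(), "total")

#' Classify an aroma profile into a scent group
#'
#' Applies an ordered decision list to the five odor-class percentages and
#' the total emission; returns the label of the first matching rule, or
#' `"unassigned"` if none match. Deterministic for fixed rules; a pure
#' function of (`class_percents`, `total_content`, `rules`).
#'
#' @param aroma An `aroma_profile`.
#' @param rules Decision list, see [default_aroma_rules()].
#' @return Group label (character scalar). Also recorded in the returned
#'   profile when assigned via [run_pipeline()].
#' @examples
#' classify_aroma(aroma_profile("x", c(9.36, 1.49, 66.30, 1.77, 0.18)))
#' @export
classify_aroma <- function(aroma, rules = default_aroma_rules()) {
  stopifnot(inherits(aroma, "aroma_profile"))
  env <- as.list(aroma$class_percents)
  env$total <- aroma$total_content
  for (rule in rules) {
    if (is.null(rule$label) || is.null(rule$when)) {
      stop("malformed rule: each rule needs 'label' and 'when'")
    }
    expr <- tryCatch(parse(text = rule$when)[[1]],
                     error = function(e) stop("malformed rule expression: ",
                                              rule$when))
    unknown <- setdiff(all.vars(expr), .rule_vars)
    if (length(unknown)) {
      stop("rule '", rule$label, "' references unknown field(s): ",
           paste(unknown, collapse = ", "))
    }
    if (isTRUE(eval(expr, envir = env))) return(rule$label)
  }
  "unassigned"
}

#' Read per-cultivar peak tables from a long-format CSV
#'
#' Expected columns: `cultivar_id`, `compound`, `peak_area`, plus the sidecar
#' columns `is_name`, `is_amount_ug`, `is_peak_area`, `sample_weight_g`
#' (constant within a cultivar).
#'
#' @param path CSV path.
#' @return Named list of [peak_table()] objects, one per cultivar.
#' @export
read_peak_tables <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cultivar_id", "compound", "peak_area", "is_name", "is_amount_ug",
            "is_peak_area", "sample_weight_g")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("peak CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  out <- lapply(split(df, df$cultivar_id), function(d) {
    peak_table(d$cultivar_id[1], d$compound, d$peak_area,
               is_name = d$is_name[1], is_amount = d$is_amount_ug[1],
               is_peak_area = d$is_peak_area[1],
               sample_weight = d$sample_weight_g[1])
  })
  out[unique(df$cultivar_id)]
}

#' Tabulate volatile profiles
#'
#' @param profiles List of `volatile_profile` objects.
#' @return Long data frame with columns `cultivar_id`, `compound`,
#'   `content_ug_per_g`, `percent`.
#' @export
profiles_to_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(cultivar_id = p$cultivar_id,
               compound = names(p$contents),
               content_ug_per_g = unname(p$contents),
               percent = unname(p$percents),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Tabulate aroma profiles
#'
#' @param aromas List of `aroma_profile` objects (with `group` filled in).
#' @return Data frame with one row per cultivar: the five class percentages
#'   (2 decimal places, matching conventional reporting), total content and
#'   group.
#' @export
aromas_to_table <- function(aromas) {
  do.call(rbind, lapply(aromas, function(a) {
    row <- as.data.frame(as.list(round(a$class_percents, 2)))
    cbind(data.frame(cultivar = a$cultivar_id, stringsAsFactors = FALSE),
          row,
          data.frame(total = a$total_content, group = a$group,
                     stringsAsFactors = FALSE))
  }))
}
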