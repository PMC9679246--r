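#' Read a life-history trait table
#'
#' CSV with header
#' `species,max_length_cm,max_lifespan_y,body_mass_g,source_quality,family`;
#' missing values as empty fields. Species names are canonicalized and
#' must be unique; all present values must be positive. Species without
#' a maximum lifespan are kept in the table (they are excluded from
#' lifespan models at dataset-assembly time, with a logged reason).
#'
#' @param path CSV file path.
#' @return data frame keyed by `species`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_traits(df)
}

#' Validate a trait data frame
#'
#' @param df data frame with at least `species`, `max_length_cm`,
#'   `max_lifespan_y`; optional `body_mass_g`, `source_quality`, `family`.
#' @return the validated data frame (canonical species names, row names
#'   set to species).
#' @export
validate_traits <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("species", "max_length_cm", "max_lifespan_y") %in% names(df)))
  df$species <- canonical_species(df$species)
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup))
    stop("duplicate species in trait table: ", paste(dup, collapse = ", "))
  for (col in intersect(c("max_length_cm", "max_lifespan_y", "body_mass_g"),
                        names(df))) {
    v <- df[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("nonpositive ", col, " for: ", paste(df$species[bad], collapse = ", "))
  }
  if (is.null(df$body_mass_g)) df$body_mass_g <- NA_real_
  if (is.null(df$source_quality)) df$source_quality <- "reliable"
  if (is.null(df$family)) df$family <- NA_character_
  ok <- df$source_quality %in% c("reliable", "low")
  if (!all(ok))
    stop("source_quality must be 'reliable' or 'low'")
  rownames(df) <- df$species
  df
}

#' Base-10 logarithm with validation
#'
#' Body size and lifespan enter the regressions log10-transformed; this
#' wrapper rejects nonpositive values with the offending species named.
#'
#' @param values named positive numeric vector (species -> value).
#' @return named numeric vector of log10 values.
#' @export
log10_transform <- function(values) {
  stopifnot(is.numeric(values))
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop("log10 undefined for nonpositive value(s): ",
         paste(names(values)[bad] %||% bad, collapse = ", "))
  log10(values)
}

#' Longevity quotient
#'
#' Observed maximum lifespan divided by the lifespan expected from body
#' mass: an ordinary least squares regression of log10(max lifespan) on
#' log10(body mass) is fitted over the species with both values, and
#' `LQ = lifespan / 10^fitted`. The fit is in-sample (each species
#' contributes to the allometric line used to predict it); species
#' lacking body mass get `NA`.
#'
#' Because OLS residuals sum to zero, the mean of log10(LQ) over fitted
#' species is exactly zero.
#'
#' @param traits a trait data frame (see [validate_traits()]).
#' @return named numeric vector of LQ values (NA where mass or lifespan
#'   is missing).
#' @export
longevity_quotient <- function(traits) {
  traits <- validate_traits(traits)
  ok <- is.finite(traits$max_lifespan_y) & is.finite(traits$body_mass_g)
  if (sum(ok) < 3L)
    stop("longevity quotient needs at least 3 species with lifespan and mass")
  lmass <- log10(traits$body_mass_g[ok])
  llife <- log10(traits$max_lifespan_y[ok])
  if (stats::sd(lmass) == 0)
    stop("body mass has zero variance; allometric fit undefined")
  fit <- stats::lm(llife ~ lmass)
  lq <- rep(NA_real_, nrow(traits))
  lq[ok] <- traits$max_lifespan_y[ok] / 10^stats::fitted(fit)
  stats::setNames(lq, traits$species)
}
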