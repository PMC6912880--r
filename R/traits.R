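#' Species trait table with Grime CSR coordinates
#'
#' Validates a per-species trait table. Vascular plants carry global CSR
#' strategy coordinates (percentages of competitor, stress-tolerator and
#' ruderal strategy summing to 100); bryophytes and lichens do not.
#' An optional `csr_class` column gives the specified (discrete) strategy
#' class (C, CR, R, SR, S, CS, CSR) assigned upstream.
#'
#' @param df data frame with columns `species`, `C`, `S`, `R`,
#'   `morph_group`, `is_vascular` and optionally `csr_class`.
#' @return The validated data frame, classed `trait_table`.
#' @export
trait_table <- function(df) {
  req <- c("species", "C", "S", "R", "morph_group", "is_vascular")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trait table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table", call. = FALSE)
  groups <- c("shrubs", "dwarf shrubs", "forbs", "graminoids",
              "pteridophytes", "bryophytes", "lichens")
  bad <- !df$morph_group %in% groups
  if (any(bad))
    stop("unknown morph_group: ", paste(unique(df$morph_group[bad]), collapse = ", "),
         call. = FALSE)
  df$is_vascular <- as.logical(df$is_vascular)
  has_csr <- !is.na(df$C) | !is.na(df$S) | !is.na(df$R)
  if (any(has_csr & !df$is_vascular))
    stop("CSR strategy values present for non-vascular species: ",
         paste(df$species[has_csr & !df$is_vascular], collapse = ", "),
         call. = FALSE)
  tot <- df$C + df$S + df$R
  off <- has_csr & (is.na(tot) | abs(tot - 100) > 1e-9)
  if (any(off))
    stop("C + S + R must equal 100 for species: ",
         paste(df$species[off], collapse = ", "), call. = FALSE)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a species trait table from CSV
#'
#' @param path CSV path with header
#'   `species,C,S,R,morph_group,is_vascular` (optionally `csr_class`).
#' @return A [trait_table()].
#' @export
read_traits <- function(path) {
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trait table to CSV
#' @param traits a [trait_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
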