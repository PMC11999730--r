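#' Unit prices for costing resource use
#'
#' Default unit prices follow the Australian public-hospital outpatient
#' pricing used in the pilot: AUD 193 per face-to-face occupational-therapy
#' appointment and AUD 177 per phone/telehealth appointment. Materials
#' (stockings, applicators, postage) in the pilot ranged from AUD 19.99 to
#' AUD 891.92; the default catalogue spans that range. Specialist VLU
#' appointments and VLU-related admissions incurred zero usage in the pilot,
#' so their unit prices default to 0 and are configurable.
#'
#' @param f2f_cost AUD per face-to-face appointment.
#' @param phone_cost AUD per phone/telehealth appointment.
#' @param specialist_cost AUD per specialist VLU appointment.
#' @param admission_cost AUD per VLU-related hospital admission.
#' @param material_catalogue Tibble with columns `item` and `unit_cost` (AUD),
#'   used to price materials recorded by label without an explicit cost.
#' @return A `price_table` object (a validated list).
#' @examples
#' price_table()
#' @export
price_table <- function(f2f_cost = 193,
                        phone_cost = 177,
                        specialist_cost = 0,
                        admission_cost = 0,
                        material_catalogue = default_material_catalogue()) {
  pt <- structure(
    list(f2f_cost = f2f_cost, phone_cost = phone_cost,
         specialist_cost = specialist_cost, admission_cost = admission_cost,
         material_catalogue = tibble::as_tibble(material_catalogue)),
    class = "price_table"
  )
  validate_price_table(pt)
}

#' @rdname price_table
#' @export
default_material_catalogue <- function() {
  tibble::tribble(
    ~item,                       ~unit_cost,
    "postage",                   19.99,
    "stocking_applicator",       59.99,
    "compression_stocking_pair", 96.45,
    "heavy_duty_applicator",     891.92,
    "stockings_and_applicators", NA_real_  # priced per record by the generator
  )
}

validate_price_table <- function(pt) {
  scalars <- c("f2f_cost", "phone_cost", "specialist_cost", "admission_cost")
  for (nm in scalars) {
    v <- pt[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("price table field '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  mc <- pt$material_catalogue
  if (!all(c("item", "unit_cost") %in% names(mc))) {
    stop("material catalogue needs columns 'item' and 'unit_cost'", call. = FALSE)
  }
  if (any(mc$unit_cost < 0, na.rm = TRUE)) {
    stop("material catalogue unit costs must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(mc$item)) {
    stop("duplicate item labels in material catalogue", call. = FALSE)
  }
  pt
}

#' @export
print.price_table <- function(x, ...) {
  cat("Price table (AUD)\n")
  cat(sprintf("  face-to-face appointment: %.2f\n", x$f2f_cost))
  cat(sprintf("  phone/telehealth appointment: %.2f\n", x$phone_cost))
  cat(sprintf("  specialist VLU appointment: %.2f\n", x$specialist_cost))
  cat(sprintf("  VLU admission: %.2f\n", x$admission_cost))
  cat(sprintf("  material catalogue: %d items\n", nrow(x$material_catalogue)))
  invisible(x)
}

#' Read / write a price table as YAML
#'
#' @param path Path to a YAML file mirroring the `price_table` fields.
#' @return For `read_price_table`, a validated `price_table`.
#' @export
read_price_table <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- if (is.null(y$material_catalogue)) {
    default_material_catalogue()
  } else {
    tibble::tibble(
      item = vapply(y$material_catalogue, function(e) as.character(e$item), character(1)),
      unit_cost = vapply(y$material_catalogue, function(e) {
        v <- e$unit_cost
        if (is.null(v) || (is.character(v) && v == "NA")) NA_real_ else as.numeric(v)
      }, numeric(1))
    )
  }
  price_table(
    f2f_cost = y$f2f_cost %||% 193,
    phone_cost = y$phone_cost %||% 177,
    specialist_cost = y$specialist_cost %||% 0,
    admission_cost = y$admission_cost %||% 0,
    material_catalogue = mc
  )
}

#' @rdname read_price_table
#' @param prices A `price_table` object.
#' @export
write_price_table <- function(prices, path) {
  validate_price_table(prices)
  y <- list(
    f2f_cost = prices$f2f_cost, phone_cost = prices$phone_cost,
    specialist_cost = prices$specialist_cost,
    admission_cost = prices$admission_cost,
    material_catalogue = lapply(seq_len(nrow(prices$material_catalogue)), function(i) {
      list(item = prices$material_catalogue$item[i],
           unit_cost = prices$material_catalogue$unit_cost[i])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
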