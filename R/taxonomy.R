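#' Food retail outlet categories and health tiers
#'
#' Seven in-scope food retail categories are defined by 6-digit NAICS code:
#' supermarkets/grocery stores (445110), fruit and vegetable markets
#' (445230), supercentres (452311), convenience stores (445120), dollar
#' stores (452319), full-service restaurants (722511) and limited-service
#' restaurants (722513). Everything else is `NON_FOOD`.
#'
#' Two registry-hygiene rules apply before the NAICS lookup is final:
#' grocery-coded establishments (445110) with fewer than five employees are
#' treated as convenience (corner) stores, and 452319 establishments
#' without the case-insensitive token "dollar" in their name are general
#' merchandise, not dollar stores, and fall out of scope.
#'
#' @return `outlet_categories()`: the seven in-scope category tokens.
#' @export
outlet_categories <- function() {
  c("SUPERMARKET_GROCERY", "FRUIT_VEG_MARKET", "SUPERCENTRE", "CONVENIENCE",
    "DOLLAR", "FULL_SERVICE_RESTAURANT", "LIMITED_SERVICE_RESTAURANT")
}

# NAICS code -> category lookup (in-scope codes only)
naics_category_map <- function() {
  c("445110" = "SUPERMARKET_GROCERY",
    "445230" = "FRUIT_VEG_MARKET",
    "452311" = "SUPERCENTRE",
    "445120" = "CONVENIENCE",
    "452319" = "DOLLAR",
    "722511" = "FULL_SERVICE_RESTAURANT",
    "722513" = "LIMITED_SERVICE_RESTAURANT")
}

#' Classify establishments into outlet categories
#'
#' Vectorised, record-local and order-independent: each record's category
#' depends only on its own NAICS code, employee count and name.
#'
#' @param naics character or numeric vector of 6-digit NAICS codes.
#' @param employees integer vector of employee counts (>= 0).
#' @param name character vector of establishment names.
#' @return character vector of category tokens (see [outlet_categories()]
#'   plus `"NON_FOOD"`).
#' @examples
#' classify_outlets("445110", 3, "Joe's Grocery")        # CONVENIENCE
#' classify_outlets("452319", 8, "Family Dollar #210")   # DOLLAR
#' classify_outlets("452319", 8, "Big Bargain Mart")     # NON_FOOD
#' @export
classify_outlets <- function(naics, employees, name) {
  naics <- trimws(as.character(naics))
  bad <- !grepl("^[0-9]{6}$", naics)
  if (any(bad))
    stop("malformed NAICS code(s) at record(s) ",
         paste(head(which(bad), 5L), collapse = ", "),
         ": ", paste(head(naics[bad], 5L), collapse = ", "), call. = FALSE)
  if (any(employees < 0, na.rm = TRUE))
    stop("negative employee count(s) at record(s) ",
         paste(head(which(employees < 0), 5L), collapse = ", "), call. = FALSE)
  cat <- unname(naics_category_map()[naics])
  cat[is.na(cat)] <- "NON_FOOD"
  # small grocery-coded stores are corner stores: fewer than five employees
  cat[naics == "445110" & employees < 5] <- "CONVENIENCE"
  # 452319 is general merchandise; only 'dollar'-named stores are in scope
  is_452319 <- naics == "452319"
  has_dollar <- grepl("dollar", trimws(name), ignore.case = TRUE)
  cat[is_452319 & !has_dollar] <- "NON_FOOD"
  cat
}

#' Map outlet categories to health tiers
#'
#' Healthy: supermarkets/grocery stores, fruit and vegetable markets,
#' supercentres. Intermediate: full-service restaurants. Unhealthy:
#' convenience stores, limited-service restaurants and (by default) dollar
#' stores; the dollar-store tier is configurable because the three-tier
#' literature places them with unhealthy outlets without a universal
#' convention.
#'
#' @param category character vector of category tokens.
#' @param dollar_tier tier for `DOLLAR` (default `"UNHEALTHY"`).
#' @return character vector in `{"HEALTHY","INTERMEDIATE","UNHEALTHY","NONE"}`.
#' @export
health_tier <- function(category,
                        dollar_tier = c("UNHEALTHY", "INTERMEDIATE", "HEALTHY")) {
  dollar_tier <- match.arg(dollar_tier)
  map <- c(SUPERMARKET_GROCERY = "HEALTHY",
           FRUIT_VEG_MARKET = "HEALTHY",
           SUPERCENTRE = "HEALTHY",
           FULL_SERVICE_RESTAURANT = "INTERMEDIATE",
           CONVENIENCE = "UNHEALTHY",
           LIMITED_SERVICE_RESTAURANT = "UNHEALTHY",
           DOLLAR = dollar_tier,
           NON_FOOD = "NONE")
  bad <- setdiff(unique(category), names(map))
  if (length(bad))
    stop("unknown outlet category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(map[category])
}

#' Classify a full establishment table
#'
#' Appends `category` and `tier` columns to an establishment registry.
#'
#' @param establishments `data.table`/data.frame with columns `naics`,
#'   `employees`, `name` (other columns pass through).
#' @param dollar_tier forwarded to [health_tier()].
#' @return a new `data.table` with `category` and `tier` appended.
#' @export
classify_establishments <- function(establishments, dollar_tier = "UNHEALTHY") {
  est <- as.data.table(establishments)
  need <- c("naics", "employees", "name")
  miss <- setdiff(need, names(est))
  if (length(miss))
    stop("establishment table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  est[, category := classify_outlets(naics, employees, name)]
  est[, tier := health_tier(category, dollar_tier = dollar_tier)]
  est[]
}
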