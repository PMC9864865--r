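#' @title Multi-worksheet report workbook
#' @description
#' The report workbook is a single-file XML Spreadsheet 2003
#' (SpreadsheetML) document — a plain-text format with genuinely named
#' worksheets that Excel and LibreOffice open directly. Numeric cells keep
#' full precision; display styles add thousands separators to base-pair
#' columns and round the IQR/median ratio to two decimals, so formatting
#' never loses data. Tab-separated mirrors of every sheet are written
#' alongside the workbook.
#' @name workbook
NULL

workbook_sheets_spec <- c("RefSeq", "Distributions", "WideAll",
                          "WideFamilies", "WideGenera", "Outliers",
                          "Alternatives")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

cell_style <- function(colname) {
  if (grepl("ratio_pct", colname)) return(" ss:StyleID=\"ratio\"")
  if (grepl("length|median|q1|q3|iqr|fence|distance|^n$|_n$", colname)) {
    return(" ss:StyleID=\"bp\"")
  }
  ""
}

format_cell <- function(value, colname) {
  style <- cell_style(colname)
  if (length(value) != 1 || is.na(value)) {
    return("<Cell><Data ss:Type=\"String\"></Data></Cell>")
  }
  if (inherits(value, "Date")) {
    return(sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
                   format(value, "%Y-%m-%d")))
  }
  if (is.numeric(value)) {
    return(sprintf("<Cell%s><Data ss:Type=\"Number\">%s</Data></Cell>",
                   style,
                   format(value, scientific = FALSE, trim = TRUE,
                          digits = 15)))
  }
  if (is.logical(value)) {
    return(sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
                   if (value) "TRUE" else "FALSE"))
  }
  sprintf("<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
          xml_escape(as.character(value)))
}

sheet_xml <- function(name, df) {
  header <- paste0(
    "<Row>",
    paste0("<Cell><Data ss:Type=\"String\">", xml_escape(names(df)),
           "</Data></Cell>", collapse = ""),
    "</Row>"
  )
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(names(df), function(col) {
      format_cell(df[[col]][i], col)
    }, "")
    paste0("<Row>", paste0(cells, collapse = ""), "</Row>")
  }, "")
  paste0("<Worksheet ss:Name=\"", xml_escape(name), "\"><Table>",
         header, paste0(body, collapse = ""), "</Table></Worksheet>")
}

#' Write the pipeline result as a report workbook
#'
#' The workbook contains exactly the seven worksheets `"RefSeq"`,
#' `"Distributions"`, `"WideAll"`, `"WideFamilies"`, `"WideGenera"`,
#' `"Outliers"`, `"Alternatives"`. The `Alternatives` sheet mirrors the
#' layout of a published comparison table: species, genus median, flagged
#' record (accession, length, publication date) and best alternative
#' (accession, length, publication date) plus the `closer` verdict. TSV
#' mirrors are written next to the workbook as `<stem>_<Sheet>.tsv`.
#'
#' @param result A `lenqc_result` from [run_pipeline()].
#' @param path Output path for the workbook (conventionally `.xml`).
#' @return Invisibly, a list with the workbook `path` and the TSV mirror
#'   paths.
#' @export
write_workbook <- function(result, path) {
  sheets <- result_sheets(result)
  stopifnot(identical(names(sheets), workbook_sheets_spec))
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<?mso-application progid=\"Excel.Sheet\"?>\n",
    "<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
    " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">",
    "<Styles>",
    "<Style ss:ID=\"bp\"><NumberFormat ss:Format=\"#,##0\"/></Style>",
    "<Style ss:ID=\"ratio\"><NumberFormat ss:Format=\"0.00\"/></Style>",
    "</Styles>",
    paste0(vapply(names(sheets), function(nm) {
      sheet_xml(nm, sheets[[nm]])
    }, ""), collapse = ""),
    "</Workbook>\n"
  )
  ok <- tryCatch({
    writeLines(xml, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    lenqc_abort(paste0("cannot write workbook to ", path, ": ",
                       conditionMessage(ok)),
                class = "io_error", parent = ok)
  }
  stem <- sub("\\.[A-Za-z]+$", "", path)
  tsvs <- write_result_tsvs(result, stem)
  invisible(list(path = path, tsv = tsvs))
}

#' List the worksheet names of a workbook
#'
#' @param path A workbook written by [write_workbook()].
#' @return Character vector of worksheet names, in file order.
#' @export
workbook_sheet_names <- function(path) {
  doc <- xml2::read_xml(path)
  ws <- xml2::xml_find_all(doc, ".//d1:Worksheet")
  xml2::xml_attr(ws, "Name")
}

#' Read one worksheet of a workbook
#'
#' The first row is taken as the header; columns whose data cells are all
#' typed `Number` come back numeric, everything else character (empty
#' strings as `NA`).
#'
#' @param path A workbook written by [write_workbook()].
#' @param sheet Worksheet name.
#' @return A tibble.
#' @export
read_workbook_sheet <- function(path, sheet) {
  doc <- xml2::read_xml(path)
  ws <- xml2::xml_find_first(
    doc, sprintf(".//d1:Worksheet[@ss:Name='%s']", sheet)
  )
  if (is.na(ws) || length(ws) == 0) {
    lenqc_abort(paste0("worksheet not found: ", sheet),
                class = "lookup_error")
  }
  rows <- xml2::xml_find_all(ws, ".//d1:Row")
  parsed <- lapply(rows, function(r) {
    data <- xml2::xml_find_all(r, ".//d1:Data")
    list(text = xml2::xml_text(data),
         type = xml2::xml_attr(data, "Type"))
  })
  header <- parsed[[1]]$text
  if (length(parsed) == 1) {
    out <- lapply(header, function(h) character(0))
    names(out) <- header
    return(tibble::as_tibble(out))
  }
  body <- parsed[-1]
  cols <- lapply(seq_along(header), function(j) {
    txt <- vapply(body, function(r) r$text[j], "")
    typ <- vapply(body, function(r) r$type[j], "")
    txt[txt == ""] <- NA_character_
    if (all(typ == "Number" | is.na(txt))) {
      as.numeric(txt)
    } else {
      txt
    }
  })
  names(cols) <- header
  tibble::as_tibble(cols)
}
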