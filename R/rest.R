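ci_error_type <- function(n) sprintf("urn:cytoscape:ci:copycat-app:v1:errors:%d", n)

ci_success <- function(data) list(data = data, errors = list())

ci_failure <- function(status, type_n, message) {
  list(data = structure(list(), names = character()),
       errors = list(list(status = status, type = ci_error_type(type_n),
                          message = message)))
}

# Accept booleans either as JSON booleans or as the strings "true"/"false"
# (the Command curl in the wild sends strings).
as_flag <- function(v, name, default = FALSE) {
  if (is.null(v)) return(default)
  if (is.logical(v) && length(v) == 1 && !is.na(v)) return(v)
  if (is.character(v) && length(v) == 1 && tolower(v) %in% c("true", "false")) {
    return(tolower(v) == "true")
  }
  cc_invalid(sprintf("parameter '%s' must be a boolean or 'true'/'false'", name))
}

as_name <- function(v, default) {
  if (is.null(v)) return(default)
  if (!is.character(v) || length(v) != 1 || !nzchar(v)) {
    cc_invalid("column parameters must be non-empty strings")
  }
  v
}

result_data <- function(res) {
  list(mappedNodeCount = res$mapped_node_count,
       unmappedNodeCount = res$unmapped_node_count,
       unmappedNodeIds = I(res$unmapped_target_ids),
       unmappedSourceNodeIds = I(res$unmapped_source_ids))
}

parse_body <- function(body) {
  if (is.null(body)) return(list())
  if (is.list(body)) return(body)
  txt <- if (is.raw(body)) rawToChar(body) else as.character(body)
  if (!nzchar(trimws(txt))) return(list())
  tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
           error = function(e) cc_invalid(
             sprintf("malformed JSON body: %s", conditionMessage(e))))
}

run_copycat_request <- function(session, source_sel, target_sel, params) {
  res <- copycat(session, source_sel, target_sel,
                 source_column = as_name(params$sourceColumn, "name"),
                 target_column = as_name(params$targetColumn, "name"),
                 select_unmapped = as_flag(params$selectUnmapped, "selectUnmapped"),
                 grid_unmapped = as_flag(params$gridUnmapped, "gridUnmapped"))
  ci_success(result_data(res))
}

#' Handle one HTTP request against a session
#'
#' The service contract, as a pure function so it can be exercised without
#' sockets. Routes (all under `/v1`, JSON in and out):
#'
#' * `PUT /v1/apply/layouts/copycat/{sourceViewSUID}/{targetViewSUID}` — the
#'   Function variant; path parts are view SUIDs or `"current"`, the body
#'   carries `sourceColumn`/`targetColumn` (default `"name"`) and the
#'   `selectUnmapped`/`gridUnmapped` flags.
#' * `POST /v1/commands/layout/copycat` — the Command variant; the body
#'   names the networks (`sourceNetwork`, `targetNetwork`) and the layout
#'   runs on each network's primary view. Boolean parameters may be the
#'   strings `"true"`/`"false"`.
#' * `GET /v1/networks`, `GET /v1/networks/{suid}/views`,
#'   `GET /v1/networks/{suid}/nodes/selected`,
#'   `GET /v1/networks/{suid}/tables/defaultnode/columns` — discovery
#'   plumbing (plain JSON arrays on success).
#'
#' Layout responses are CIResponse envelopes: `{"data": {...}, "errors":
#' []}` on success; on failure `data` is empty and `errors[0].status`
#' carries the HTTP status — 404 for unresolvable views/networks and for
#' mapping-column problems (absent column, non-matchable or mismatched
#' kinds), 400 for malformed bodies and for identical source and target.
#'
#' @param session A [copycat_session()].
#' @param method HTTP method string.
#' @param path Request path, e.g. `"/v1/networks"`.
#' @param body Request body: JSON text, raw bytes, or an R list.
#' @return List with `status` (integer) and `body` (R object; serialize
#'   with [rest_serialize()]).
#' @export
rest_handle <- function(session, method, path, body = NULL) {
  parts <- strsplit(sub("^/+", "", path), "/", fixed = TRUE)[[1]]
  ok <- function(b) list(status = 200L, body = b)
  respond_error <- function(e) {
    if (inherits(e, "copycat_not_found") || inherits(e, "copycat_column_error")) {
      list(status = 404L, body = ci_failure(404L, 1L, conditionMessage(e)))
    } else if (inherits(e, "copycat_validation")) {
      list(status = 400L, body = ci_failure(400L, 2L, conditionMessage(e)))
    } else {
      list(status = 500L, body = ci_failure(500L, 3L, conditionMessage(e)))
    }
  }

  tryCatch({
    if (method == "PUT" && length(parts) == 6 &&
        identical(parts[1:4], c("v1", "apply", "layouts", "copycat"))) {
      params <- parse_body(body)
      return(ok(run_copycat_request(session, parts[[5]], parts[[6]], params)))
    }
    if (method == "POST" && length(parts) == 4 &&
        identical(parts[1:4], c("v1", "commands", "layout", "copycat"))) {
      params <- parse_body(body)
      if (is.null(params$sourceNetwork) || is.null(params$targetNetwork)) {
        cc_invalid("sourceNetwork and targetNetwork are required")
      }
      sv <- find_view_by_network_name(session, params$sourceNetwork)
      tv <- find_view_by_network_name(session, params$targetNetwork)
      return(ok(run_copycat_request(session, sv$view_suid, tv$view_suid, params)))
    }
    if (method == "GET" && length(parts) == 2 && identical(parts, c("v1", "networks"))) {
      return(ok(I(list_networks(session))))
    }
    if (method == "GET" && length(parts) == 4 && parts[[1]] == "v1" &&
        parts[[2]] == "networks" && parts[[4]] == "views") {
      return(ok(I(list_views(session, req_suid(parts[[3]])))))
    }
    if (method == "GET" && length(parts) == 5 && parts[[1]] == "v1" &&
        parts[[2]] == "networks" && parts[[4]] == "nodes" && parts[[5]] == "selected") {
      return(ok(I(selected_nodes(session, req_suid(parts[[3]])))))
    }
    if (method == "GET" && length(parts) == 6 && parts[[1]] == "v1" &&
        parts[[2]] == "networks" && identical(parts[4:6],
                                              c("tables", "defaultnode", "columns"))) {
      g <- get_network(session, req_suid(parts[[3]]))
      cols <- lapply(seq_len(nrow(g$columns)), function(j) {
        list(name = g$columns$name[[j]],
             type = switch(g$columns$kind[[j]],
                           string = "String", integer = "Integer", "Double"))
      })
      return(ok(cols))
    }
    cc_not_found(sprintf("no route for %s %s", method, path))
  }, copycat_error = respond_error, error = respond_error)
}

req_suid <- function(part) {
  id <- suppressWarnings(as.integer(part))
  if (is.na(id)) cc_not_found(sprintf("'%s' is not an SUID", part))
  id
}

#' Serialize a handler body to JSON text
#'
#' @param body The `body` element returned by [rest_handle()].
#' @return A JSON string (scalars unboxed, arrays kept as arrays, full
#'   numeric precision).
#' @export
rest_serialize <- function(body) {
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Serve a session over HTTP
#'
#' Binds the routes of [rest_handle()] on a local port (default 1234, the
#' customary `rest.port`). Blocks while serving; set `max_seconds` for a
#' self-terminating server (useful when spawning one from a test or script).
#'
#' @param session A [copycat_session()].
#' @param port TCP port.
#' @param host Bind address.
#' @param max_seconds Serve for at most this many seconds (default `Inf`).
#' @return Invisibly, the number of requests served.
#' @export
rest_serve <- function(session, port = 1234, host = "127.0.0.1",
                       max_seconds = Inf) {
  served <- 0L
  app <- list(call = function(req) {
    body <- tryCatch(req$rook.input$read(), error = function(e) NULL)
    resp <- rest_handle(session, req$REQUEST_METHOD, req$PATH_INFO, body)
    served <<- served + 1L
    list(status = resp$status,
         headers = list("Content-Type" = "application/json"),
         body = rest_serialize(resp$body))
  })
  srv <- httpuv::startServer(host, port, app)
  on.exit(httpuv::stopServer(srv), add = TRUE)
  t0 <- Sys.time()
  while (as.numeric(difftime(Sys.time(), t0, units = "secs")) < max_seconds) {
    httpuv::service(250)
  }
  invisible(served)
}

#' Parse a Command Tool line for the layout
#'
#' Turns a one-line command script entry such as
#' `layout copycat sourceNetwork=a.sif targetNetwork=b.sif selectUnmapped=true`
#' into the parameter list the Command endpoint consumes. Values may be
#' double-quoted to contain spaces.
#'
#' @param line The command line.
#' @return Named list of string parameters.
#' @export
parse_command_string <- function(line) {
  line <- trimws(line)
  if (!grepl("^layout\\s+copycat(\\s|$)", line)) {
    cc_invalid("not a 'layout copycat' command line")
  }
  rest <- trimws(sub("^layout\\s+copycat", "", line))
  if (!nzchar(rest)) return(list())
  m <- gregexpr('[A-Za-z][A-Za-z0-9]*=(?:"[^"]*"|[^\\s"]+)', rest, perl = TRUE)[[1]]
  toks <- regmatches(rest, list(m))[[1]]
  if (length(toks) == 0) cc_invalid("no key=value pairs in command line")
  keys <- sub("=.*$", "", toks)
  vals <- sub('^[^=]*=', "", toks)
  vals <- sub('^"(.*)"$', "\\1", vals)
  stats::setNames(as.list(vals), keys)
}
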