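#' Synthetic hepatic-disorder term list
#'
#' A synthetic stand-in for a standardised MedDRA query (SMQ) covering
#' drug-related hepatic disorders. MedDRA is licensed and its SMQ term
#' lists cannot be redistributed, so this list contains generic
#' liver-injury reaction names in preferred-term style. It is the default
#' event-term set of the report simulator and of the bundled example data;
#' analyses of real data should load the licensed SMQ with [read_smq()].
#'
#' @return Character vector of reaction preferred terms.
#' @seealso [read_smq()], [smq_termset()]
#' @export
#' @examples
#' head(hepatic_smq_example())
hepatic_smq_example <- function() {
  c(
    "Hepatitis", "Hepatitis acute", "Hepatitis fulminant", "Hepatitis toxic",
    "Hepatitis cholestatic", "Hepatocellular injury", "Liver injury",
    "Drug-induced liver injury", "Liver disorder", "Hepatic failure",
    "Hepatic failure acute", "Hepatic necrosis", "Hepatotoxicity",
    "Hepatic steatosis", "Hepatomegaly", "Cholestasis", "Jaundice",
    "Jaundice cholestatic", "Hyperbilirubinaemia", "Blood bilirubin increased",
    "Alanine aminotransferase increased", "Aspartate aminotransferase increased",
    "Gamma-glutamyltransferase increased", "Blood alkaline phosphatase increased",
    "Hepatic enzyme increased", "Liver function test abnormal",
    "Transaminases increased", "Hepatic cirrhosis", "Hepatic fibrosis",
    "Hepatorenal syndrome", "Hepatic encephalopathy", "Ascites",
    "Hepatitis chronic", "Liver transplant", "Hepatic cytolysis",
    "Ammonia increased"
  )
}

# Non-hepatic filler reactions drawn for every simulated case. None of these
# may match the hepatic term list above.
filler_reaction_terms <- c(
  "Nausea", "Vomiting", "Headache", "Dizziness", "Somnolence", "Insomnia",
  "Tremor", "Akathisia", "Weight increased", "Constipation", "Dry mouth",
  "Fatigue", "Anxiety", "Agitation", "Rash", "Pruritus", "Tachycardia",
  "Hypotension", "Blurred vision", "Diarrhoea", "Dyspnoea", "Pyrexia",
  "Arthralgia", "Myalgia", "Hyperglycaemia", "Hyperprolactinaemia",
  "Dystonia", "Sedation", "Palpitations", "Oedema peripheral"
)

# Background comparator drugs so that every simulated case carries at least
# one drug row and the non-case background is populated.
background_drug_pool <- sprintf("comparator_%02d", 1:12)

# whitespace-squished, lower-cased term for case-insensitive matching
normalize_term <- function(x) {
  tolower(stringr::str_squish(x))
}
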