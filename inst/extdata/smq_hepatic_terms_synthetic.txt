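# Synthetic stand-in for a hepatic-disorders standardised query term list.
# One reaction preferred term per line; '#' starts a comment.
Hepatitis
Hepatitis acute
Hepatitis fulminant
Hepatitis toxic
Hepatitis cholestatic
Hepatocellular injury
Liver injury
Drug-induced liver injury
Liver disorder
Hepatic failure
Hepatic failure acute
Hepatic necrosis
Hepatotoxicity
Hepatic steatosis
Hepatomegaly
Cholestasis
Jaundice
Jaundice cholestatic
Hyperbilirubinaemia
Blood bilirubin increased
Alanine aminotransferase increased
Aspartate aminotransferase increased
Gamma-glutamyltransferase increased
Blood alkaline phosphatase increased
Hepatic enzyme increased
Liver function test abnormal
Transaminases increased
Hepatic cirrhosis
Hepatic fibrosis
Hepatorenal syndrome
Hepatic encephalopathy
Ascites
Hepatitis chronic
Liver transplant
Hepatic cytolysis
Ammonia increased
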