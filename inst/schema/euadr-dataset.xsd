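<?xml version="1.0" encoding="UTF-8"?>
<!--
  Normative machine-readable schema for the adrsub provider interchange
  dialect. The dialect covers three concerns:

    * monitoring  - a status code per output document (0 = success;
                    41 = internal database-connection failure; codes are
                    drawn from the package's closed status registry)
    * scoring     - one score per signal, a decimal in [0,1], serialized
                    with exactly 6 fractional digits
    * annotation  - typed evidence links (pubmed, uniprot, smiles,
                    reactome, resource, other)

  Canonical documents additionally fix the element order as declared
  here, use two-space indentation, UTF-8 and LF line endings. The
  optional <stats> block carries researcher-imported mining statistics,
  passed through untouched by every provider. Rule ids used by the
  package validator (validate_document) map one-to-one onto the
  constraints expressed or noted below.
-->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">

  <xs:simpleType name="unitScore">
    <xs:restriction base="xs:decimal">
      <xs:minInclusive value="0"/>
      <xs:maxInclusive value="1"/>
      <xs:fractionDigits value="6"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="atcCode">
    <!-- rule: atc-format -->
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Z]|[A-Z][0-9]{2}|[A-Z][0-9]{2}[A-Z]|[A-Z][0-9]{2}[A-Z]{2}|[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="annotationKind">
    <!-- rule: annotation-kind -->
    <xs:restriction base="xs:string">
      <xs:enumeration value="pubmed"/>
      <xs:enumeration value="uniprot"/>
      <xs:enumeration value="smiles"/>
      <xs:enumeration value="reactome"/>
      <xs:enumeration value="resource"/>
      <xs:enumeration value="other"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="nonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="euadr-dataset">
    <xs:complexType>
      <xs:sequence>
        <!-- rules: monitoring-required (direction=output),
             monitoring-unexpected (direction=input),
             status-registered (code must be in the status registry) -->
        <xs:element name="monitoring" minOccurs="0" maxOccurs="1">
          <xs:complexType>
            <xs:attribute name="code" type="xs:nonNegativeInteger"
                          use="required"/>
            <xs:attribute name="message" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <!-- rule: signals-required -->
        <xs:element name="signals" minOccurs="1" maxOccurs="1">
          <xs:complexType>
            <xs:sequence>
              <!-- rules: pair-unique (no duplicate drug/event pair),
                   element-order (children in declared order) -->
              <xs:element name="signal" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="drug">
                      <xs:complexType>
                        <xs:attribute name="atc" type="atcCode"
                                      use="required"/>
                        <xs:attribute name="name" type="xs:string"/>
                      </xs:complexType>
                    </xs:element>
                    <!-- rule: event-code-nonempty -->
                    <xs:element name="event">
                      <xs:complexType>
                        <xs:attribute name="code" type="nonEmptyString"
                                      use="required"/>
                        <xs:attribute name="name" type="xs:string"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="stats" minOccurs="0">
                      <xs:complexType>
                        <xs:sequence>
                          <!-- rule: stat-numeric -->
                          <xs:element name="stat" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:attribute name="name"
                                            type="nonEmptyString"
                                            use="required"/>
                              <xs:attribute name="value" type="xs:decimal"
                                            use="required"/>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                    <!-- rules: score-range, score-in-input -->
                    <xs:element name="score" minOccurs="0">
                      <xs:complexType>
                        <xs:attribute name="value" type="unitScore"
                                      use="required"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="annotations" minOccurs="0">
                      <xs:complexType>
                        <xs:sequence>
                          <!-- rule: annotation-value -->
                          <xs:element name="annotation"
                                      maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:attribute name="kind"
                                            type="annotationKind"
                                            use="required"/>
                              <xs:attribute name="value"
                                            type="nonEmptyString"
                                            use="required"/>
                              <xs:attribute name="label"
                                            type="xs:string"/>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <!-- rule: direction-attr -->
      <xs:attribute name="direction" use="required">
        <xs:simpleType>
          <xs:restriction base="xs:string">
            <xs:enumeration value="input"/>
            <xs:enumeration value="output"/>
          </xs:restriction>
        </xs:simpleType>
      </xs:attribute>
      <!-- rules: provider-required, provider-unexpected -->
      <xs:attribute name="provider" type="nonEmptyString"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
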